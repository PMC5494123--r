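# Trapezoidal fuzzification of the three health indicators (core
# temperature, dehydration percentage, heart rate) into the 12 fuzzy
# symptoms driving the health-state machine.

#' Trapezoidal membership function
#'
#' Zero outside `[a, d]`, linear ramps on `[a, b]` and `[c, d]`, exactly 1 on
#' the plateau `[b, c]`. Infinite `a = b = -Inf` (or `c`/`d = Inf`) open the
#' corresponding side as an unbounded plateau.
#'
#' @param x numeric vector of indicator values.
#' @param a,b,c,d ordered breakpoints, `a <= b <= c <= d`.
#' @return membership degrees in \[0, 1\].
#' @export
#' @examples
#' trapezoid(c(37.0, 37.7, 38.2), 37.2, 37.6, 38.0, 38.4)
trapezoid <- function(x, a, b, c, d) {
  if (!(a <= b && b <= c && c <= d)) {
    abort_field("breakpoints", "must satisfy a <= b <= c <= d")
  }
  up <- if (is.infinite(b - a)) rep(1, length(x)) else (x - a) / (b - a)
  up[x >= b] <- 1
  down <- if (is.infinite(d - c)) rep(1, length(x)) else (d - x) / (d - c)
  down[x <= c] <- 1
  pmin(pmax(pmin(up, down), 0), 1)
}

# symptom -> state-letter map and severity used for tie-breaking (higher =
# more severe; ties at equal degree resolve toward the more severe symptom).
.symptom_meta <- tibble::tribble(
  ~indicator, ~symptom, ~letter, ~severity, ~label,
  "ct", "lt",  "H", 1, "low temperature",
  "ct", "nt",  "N", 0, "normal temperature",
  "ct", "sht", "F", 1, "slightly high temperature",
  "ct", "mht", "F", 2, "moderate high temperature",
  "ct", "ht",  "F", 3, "high temperature",
  "da", "nd",  "N", 0, "nondehydration",
  "da", "mid", "D", 1, "mild dehydration",
  "da", "mod", "D", 2, "moderate dehydration",
  "da", "sd",  "D", 3, "severe dehydration",
  "hr", "lhr", "B", 1, "low heart rate",
  "hr", "nhr", "N", 0, "normal heart rate",
  "hr", "hhr", "T", 1, "high heart rate")

#' Default fuzzy-set breakpoint table
#'
#' Trapezoidal breakpoints for the 12 symptoms. Core temperature is in
#' degrees C, dehydration in percent of body mass, heart rate in beats/min
#' with the normal/high boundary anchored at the subject's target (THR) and
#' maximum (MHR) heart rates. All breakpoints can be overridden through the
#' scenario's `fuzzy_sets` field.
#'
#' Anchors: membership of `sht` is 1 at 37.7 degC, of `mht` at 38.8, of `ht`
#' at 40.0; high heart rate onsets at THR.
#'
#' @param thr target heart rate, beats/min.
#' @param mhr maximum heart rate, beats/min; must exceed `thr`.
#' @return tibble with columns `indicator`, `symptom`, `letter`, `severity`,
#'   `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' default_fuzzy_sets(160.04, 181.55)
default_fuzzy_sets <- function(thr, mhr) {
  if (!(thr < mhr)) abort_field("thr", "must be below mhr")
  bp <- tibble::tribble(
    ~symptom, ~a, ~b, ~c, ~d,
    "lt",  -Inf, -Inf, 35.5, 36.3,
    "nt",  35.5, 36.3, 37.2, 37.8,
    "sht", 37.2, 37.6, 38.0, 38.4,
    "mht", 38.0, 38.4, 39.2, 39.6,
    "ht",  39.2, 39.6, Inf, Inf,
    "nd",  -Inf, -Inf, 0.8, 1.2,
    "mid", 0.8, 1.2, 2.5, 3.0,
    "mod", 2.5, 3.0, 4.5, 5.0,
    "sd",  4.5, 5.0, Inf, Inf,
    "lhr", -Inf, -Inf, 50, 60,
    "nhr", 50, 60, thr, thr + 10,
    "hhr", thr, thr + 10, mhr + 20, Inf)
  dplyr::left_join(.symptom_meta, bp, by = "symptom")
}

scenario_fuzzy_sets <- function(sc) {
  sc$fuzzy_sets %||% default_fuzzy_sets(sc$derived$thr, sc$derived$mhr)
}

#' Assess the fuzzy symptoms at one time point
#'
#' Evaluates all 12 trapezoidal memberships and picks, per indicator, the
#' dominant symptom (largest degree; ties broken toward the more severe
#' symptom).
#'
#' @param t_cr core temperature, degrees C.
#' @param da_pct dehydration, percent of body mass.
#' @param hr heart rate, beats/min.
#' @param sets breakpoint table from [default_fuzzy_sets()] (or an override).
#' @return a list of class `symptom_assessment`: `degrees` (named numeric,
#'   12 symptoms), `dominant` and `dominant_degree` (named by indicator
#'   `ct`/`da`/`hr`).
#' @export
#' @examples
#' sets <- default_fuzzy_sets(160.04, 181.55)
#' assess_symptoms(37.7, 0, 74, sets)$dominant
assess_symptoms <- function(t_cr, da_pct, hr, sets) {
  stopifnot(is.finite(t_cr), is.finite(da_pct), is.finite(hr))
  x <- c(ct = t_cr, da = da_pct, hr = hr)[sets$indicator]
  deg <- pmap_dbl(list(x, sets$a, sets$b, sets$c, sets$d), trapezoid)
  degrees <- setNames(deg, sets$symptom)
  dominant <- dominant_degree <- list()
  for (ind in c("ct", "da", "hr")) {
    idx <- which(sets$indicator == ind)
    ord <- idx[order(-deg[idx], -sets$severity[idx])]
    dominant[[ind]] <- sets$symptom[ord[1]]
    dominant_degree[[ind]] <- unname(deg[ord[1]])
  }
  structure(list(degrees = degrees,
                 dominant = unlist(dominant),
                 dominant_degree = unlist(dominant_degree)),
            class = "symptom_assessment")
}

#' Fuzzify a table of indicator values
#'
#' Data-frame-first wrapper around [assess_symptoms()]: takes a tibble with
#' columns `t_cr_c`, `da_pct` and `hr_bpm` and returns it augmented with the
#' 12 membership-degree columns and the dominant symptom per indicator.
#'
#' @param data tibble with columns `t_cr_c`, `da_pct`, `hr_bpm` (other columns
#'   pass through).
#' @param sets breakpoint table from [default_fuzzy_sets()].
#' @return tibble: input columns plus one column per symptom code and
#'   `ct_symptom`, `da_symptom`, `hr_symptom`.
#' @export
fuzzify <- function(data, sets) {
  stopifnot(all(c("t_cr_c", "da_pct", "hr_bpm") %in% names(data)))
  res <- purrr::pmap(
    list(data$t_cr_c, data$da_pct, data$hr_bpm),
    function(tc, da, hr) {
      a <- assess_symptoms(tc, da, hr, sets)
      c(as.list(a$degrees),
        list(ct_symptom = a$dominant[["ct"]],
             da_symptom = a$dominant[["da"]],
             hr_symptom = a$dominant[["hr"]]))
    })
  dplyr::bind_cols(data, dplyr::bind_rows(res))
}
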