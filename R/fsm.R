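# The fuzzy finite state machine over health states. A state is a three-
# letter code: core temperature H/N/F (hypo-/normo-/hyperthermia), dehydration
# N/D, heart rate B/N/T (brady-/normal/tachycardia). Accepting a symptom
# rewrites the letter of its own indicator only; transition weights default
# to 1.

.letter_sets <- list(ct = c("H", "N", "F"), da = c("N", "D"),
                     hr = c("B", "N", "T"))

# Possible syndromes per health state (clinical annotation attached to each
# code).
.syndromes <- c(
  HNB = "Hypothermia, arrhythmia",
  HNN = "Hypothermia",
  HNT = "Hypothermia, arrhythmia",
  HDB = "Hypothermia, dehydration, arrhythmia",
  HDN = "Hypothermia, dehydration",
  HDT = "Hypothermia, dehydration, arrhythmia",
  NNB = "Bradycardia",
  NNN = "Normal",
  NNT = "Tachycardia",
  NDB = "Dehydration, arrhythmia",
  NDN = "Dehydration",
  NDT = "Dehydration, arrhythmia",
  FNB = "Hyperthermia, arrhythmia",
  FNN = "Hyperthermia",
  FNT = "Hyperthermia, arrhythmia",
  FDB = "Hyperthermia, dehydration, heatstroke, syncope, arrhythmia",
  FDN = "Hyperthermia, dehydration, heatstroke, syncope",
  FDT = "Hyperthermia, heatstroke, syncope, arrhythmia, shock")

#' Build the health-state machine
#'
#' Enumerates the 12-symptom alphabet and the 18 health states (Cartesian
#' product of the three indicator letter sets), the transition function
#' (replace the symptom's indicator letter) and unit transition weights.
#'
#' @param weights optional tibble with columns `from`, `symptom`, `weight`
#'   overriding individual transition weights (all others stay 1).
#' @return a list of class `health_fsm`: `symptoms` (tibble), `states`
#'   (tibble with `code` and `syndromes`), `transitions` (tibble `from`,
#'   `symptom`, `to`, `weight`, 216 rows).
#' @export
#' @examples
#' fsm <- build_fsm()
#' nrow(fsm$states) # 18
build_fsm <- function(weights = NULL) {
  symptoms <- .symptom_meta
  grid <- expand.grid(hr = .letter_sets$hr, da = .letter_sets$da,
                      ct = .letter_sets$ct, stringsAsFactors = FALSE)
  codes <- paste0(grid$ct, grid$da, grid$hr)
  states <- tibble::tibble(code = codes,
                           ct = grid$ct, da = grid$da, hr = grid$hr,
                           syndromes = unname(.syndromes[codes]))
  pos <- c(ct = 1, da = 2, hr = 3)
  trans <- tidyr::expand_grid(from = states$code,
                              symptom = symptoms$symptom)
  meta <- symptoms[match(trans$symptom, symptoms$symptom), ]
  to <- trans$from
  substr(to, pos[meta$indicator], pos[meta$indicator]) <- meta$letter
  trans$to <- to
  trans$weight <- 1
  if (!is.null(weights)) {
    stopifnot(all(c("from", "symptom", "weight") %in% names(weights)))
    key <- paste(trans$from, trans$symptom)
    okey <- paste(weights$from, weights$symptom)
    hit <- match(key, okey)
    trans$weight[!is.na(hit)] <- weights$weight[hit[!is.na(hit)]]
  }
  structure(list(symptoms = symptoms, states = states, transitions = trans),
            class = "health_fsm")
}

#' @export
print.health_fsm <- function(x, ...) {
  cat(sprintf("<health_fsm> %d symptoms, %d states, %d transitions\n",
              nrow(x$symptoms), nrow(x$states), nrow(x$transitions)))
  invisible(x)
}

#' Apply the transition function
#'
#' @param fsm a [build_fsm()] machine.
#' @param state current 3-letter state code.
#' @param symptom accepted symptom code.
#' @return the successor state code.
#' @export
#' @examples
#' fsm_transition(build_fsm(), "NNN", "hhr") # "NNT"
fsm_transition <- function(fsm, state, symptom) {
  hit <- fsm$transitions$from == state & fsm$transitions$symptom == symptom
  if (!any(hit)) {
    abort(sprintf("no transition for state '%s' and symptom '%s'",
                  state, symptom))
  }
  fsm$transitions$to[which(hit)[1]]
}

#' State transition probability of one indicator
#'
#' Max-min composition over the indicator's symptom set: the largest
#' `min(degree, weight)` over the transitions leaving `state`.
#'
#' @param assessment a [assess_symptoms()] result (or a named degree vector
#'   covering the indicator's symptoms).
#' @param indicator `"ct"`, `"da"` or `"hr"`.
#' @param fsm a [build_fsm()] machine.
#' @param state current state code (selects the applicable weights).
#' @return transition probability in \[0, 1\].
#' @export
transition_probability <- function(assessment, indicator, fsm,
                                   state = "NNN") {
  degrees <- if (inherits(assessment, "symptom_assessment")) {
    assessment$degrees
  } else {
    assessment
  }
  syms <- fsm$symptoms$symptom[fsm$symptoms$indicator == indicator]
  syms <- intersect(syms, names(degrees))
  if (length(syms) == 0) {
    abort_field("assessment", sprintf("has no degrees for indicator '%s'",
                                      indicator))
  }
  tr <- fsm$transitions[fsm$transitions$from == state &
                          fsm$transitions$symptom %in% syms, ]
  w <- setNames(tr$weight, tr$symptom)[syms]
  max(pmin(unname(degrees[syms]), w))
}

#' Per-indicator state probability update
#'
#' When the indicator's state letter is unchanged the previous probability is
#' averaged with the transition probability; when it changes, the complement
#' of the previous probability is averaged with the transition probability.
#'
#' @param prev previous indicator probability in \[0, 1\].
#' @param trans transition probability in \[0, 1\].
#' @param changed logical: did this indicator's letter change at this tick?
#' @return updated probability in \[0, 1\].
#' @export
#' @examples
#' update_indicator_probability(0.5, 1, changed = FALSE) # 0.75
update_indicator_probability <- function(prev, trans, changed) {
  check_range(prev, "prev", 0, 1)
  check_range(trans, "trans", 0, 1)
  if (changed) (1 - prev + trans) / 2 else (prev + trans) / 2
}

#' Overall health-state probability update
#'
#' Combines the three indicators into one probability for the current state.
#' Under the default `"mean"` method each unchanged indicator contributes
#' `(mu_i + mu_overall) / 2`, each changed indicator `(1 - mu_i) / 2`, and the
#' result is their mean; this reading reproduces the worked transition tables
#' (see the methods vignette). The `"printed"` method is the literal
#' `1/(N+1)` + `1/M` normalisation kept for comparison.
#'
#' @param prev_overall previous overall probability.
#' @param indicator_probs_prev numeric length-3: per-indicator probabilities
#'   at the previous tick (order ct, da, hr).
#' @param changed logical length-3 (or indices): which indicators changed
#'   state letter.
#' @param method `"mean"` (default) or `"printed"`.
#' @return updated overall probability in \[0, 1\].
#' @export
#' @examples
#' update_overall_probability(1, c(0.7, 1, 1), c(FALSE, FALSE, FALSE)) # 0.95
update_overall_probability <- function(prev_overall, indicator_probs_prev,
                                       changed,
                                       method = c("mean", "printed")) {
  method <- match.arg(method)
  check_range(prev_overall, "prev_overall", 0, 1)
  stopifnot(length(indicator_probs_prev) == 3)
  for (p in indicator_probs_prev) check_range(p, "indicator_probs_prev", 0, 1)
  if (!is.logical(changed)) {
    changed <- seq_len(3) %in% changed
  }
  stopifnot(length(changed) == 3)
  contrib <- ifelse(changed,
                    (1 - indicator_probs_prev) / 2,
                    (indicator_probs_prev + prev_overall) / 2)
  if (method == "mean") {
    return(mean(contrib))
  }
  n_unchanged <- sum(!changed)
  n_changed <- sum(changed)
  val <- sum(contrib[!changed]) / (n_unchanged + 1)
  if (n_changed > 0) val <- val + sum(contrib[changed]) / n_changed
  min(max(val, 0), 1)
}

#' One tick of the health-state machine
#'
#' For each indicator: the dominant symptom proposes a successor letter via
#' the transition function; the transition probability is the max-min
#' composition over the indicator's symptoms; the indicator probability is
#' updated with [update_indicator_probability()] and the overall probability
#' with [update_overall_probability()] (which uses the indicator
#' probabilities from the previous tick).
#'
#' @param current list with `state` (code), `ind_probs` (named ct/da/hr),
#'   `overall`.
#' @param assessment a [assess_symptoms()] result.
#' @param fsm a [build_fsm()] machine.
#' @param method overall update method, see [update_overall_probability()].
#' @return a list like `current` plus `changed`, `trans_probs`, `dominant`,
#'   `dominant_degree`.
#' @export
fsm_step <- function(current, assessment, fsm, method = "mean") {
  inds <- c("ct", "da", "hr")
  pos <- c(ct = 1, da = 2, hr = 3)
  state <- current$state
  if (!state %in% fsm$states$code) {
    abort(sprintf("unknown health state '%s'", state))
  }
  new_letters <- character(3)
  changed <- logical(3)
  trans_probs <- numeric(3)
  names(new_letters) <- names(changed) <- names(trans_probs) <- inds
  for (ind in inds) {
    dom <- assessment$dominant[[ind]]
    succ <- fsm_transition(fsm, state, dom)
    new_letters[ind] <- substr(succ, pos[ind], pos[ind])
    changed[ind] <- new_letters[ind] != substr(state, pos[ind], pos[ind])
    trans_probs[ind] <- transition_probability(assessment, ind, fsm, state)
  }
  overall <- update_overall_probability(current$overall,
                                        unname(current$ind_probs[inds]),
                                        unname(changed), method = method)
  ind_probs <- mapply(update_indicator_probability,
                      current$ind_probs[inds], trans_probs, changed)
  list(state = paste0(new_letters["ct"], new_letters["da"], new_letters["hr"]),
       ind_probs = setNames(ind_probs, inds),
       overall = overall,
       changed = changed,
       trans_probs = trans_probs,
       dominant = assessment$dominant,
       dominant_degree = assessment$dominant_degree)
}

#' Export the state machine as JSON
#'
#' @param fsm a [build_fsm()] machine.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
export_fsm <- function(fsm, path) {
  jsonlite::write_json(
    list(symptoms = fsm$symptoms, states = fsm$states,
         transitions = fsm$transitions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
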