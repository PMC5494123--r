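# End-to-end driver: scenario -> thermal + heart-rate simulation -> health
# trace -> summary, with optional file outputs; built-in case fixtures and a
# seeded synthetic-scenario generator for property testing.

#' Run a scenario end to end
#'
#' Simulates the two-node thermal response and the heart-rate model, derives
#' the health-state transition sequence, and summarises the run. When
#' `out_dir` is given, writes `timeseries.csv` (indicators at the assessment
#' cadence), `trace.csv`, `fsm.json` and `summary.json` there.
#'
#' @param sc a [scenario()] or the path to a scenario config file.
#' @param out_dir optional output directory (created if missing).
#' @param full_resolution also keep the full-step thermal series in the
#'   result (default TRUE; the CSV output is always at the cadence).
#' @return an object of class `health_sim`: list with `scenario`, `thermal`,
#'   `heart_rate`, `trace`, `indicators` (cadence-aligned tibble) and
#'   `summary`.
#' @export
#' @examples
#' res <- run_scenario(case_scenario(2))
#' res$summary$states_visited
run_scenario <- function(sc, out_dir = NULL, full_resolution = TRUE) {
  if (is.character(sc)) sc <- load_scenario(sc)
  stopifnot(inherits(sc, "scenario"))
  thermal <- simulate_thermal(sc)
  heart_rate <- integrate_hr(sc$params, sc$derived$u,
                             sc$exercise$duration_min,
                             dt = sc$params$hr_dt,
                             hr_rest = sc$subject$hr_rest)
  fsm <- build_fsm()
  trace <- run_health_sequence(thermal, heart_rate, sc, fsm)

  ticks <- seq(0, sc$exercise$duration_min, by = sc$params$fsm_cadence)
  th_idx <- match(round(ticks, 9), round(thermal$t_min, 9))
  hr_idx <- match(round(ticks, 9), round(heart_rate$t_min, 9))
  indicators <- tibble::tibble(
    t_min = ticks,
    t_sk_c = thermal$t_sk_c[th_idx],
    t_cr_c = thermal$t_cr_c[th_idx],
    m_rsw_g_min = thermal$m_rsw_g_min[th_idx],
    da_g = thermal$da_g[th_idx],
    da_pct_body_mass = thermal$da_pct[th_idx],
    hr_bpm = heart_rate$hr_bpm[hr_idx])

  states_visited <- rle(trace$state)$values
  syn <- setNames(fsm$states$syndromes, fsm$states$code)
  warn_states <- states_visited[syn[states_visited] != "Normal"]
  warnings <- if (length(warn_states)) {
    sprintf("entered state %s (possible: %s)", warn_states,
            syn[warn_states])
  } else {
    character(0)
  }
  final <- trace[nrow(trace), ]
  summary <- list(
    scenario = sc$name,
    final_state = final$state,
    final_probability = final$overall_prob,
    states_visited = states_visited,
    peak_t_cr_c = max(thermal$t_cr_c),
    peak_hr_bpm = max(heart_rate$hr_bpm),
    total_da_g = max(thermal$da_g),
    da_pct_body_mass = max(thermal$da_pct),
    mhr = sc$derived$mhr,
    thr = sc$derived$thr,
    warnings = warnings)

  res <- structure(list(scenario = sc,
                        thermal = if (full_resolution) thermal,
                        heart_rate = if (full_resolution) heart_rate,
                        indicators = indicators,
                        trace = trace,
                        fsm = fsm,
                        summary = summary),
                   class = "health_sim")
  if (!is.null(out_dir)) write_run_outputs(res, out_dir)
  res
}

#' @export
print.health_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<health_sim> %s\n", s$scenario))
  cat(sprintf("  states: %s (final probability %.2f)\n",
              paste(s$states_visited, collapse = " -> "),
              s$final_probability))
  cat(sprintf("  peak T_cr %.2f degC | peak HR %.1f bpm | sweat loss %.0f g (%.2f%% body mass)\n",
              s$peak_t_cr_c, s$peak_hr_bpm, s$total_da_g,
              s$da_pct_body_mass))
  for (w in s$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), NA, formatC(round_half_up(x, digits), digits = digits,
                               format = "f"))
}

write_run_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ind <- res$indicators
  ind_out <- tibble::tibble(
    t_min = fmt_num(ind$t_min, 2),
    T_sk_C = fmt_num(ind$t_sk_c, 2),
    T_cr_C = fmt_num(ind$t_cr_c, 2),
    m_rsw_g_min = fmt_num(ind$m_rsw_g_min, 2),
    DA_g = fmt_num(ind$da_g, 2),
    DA_pct_body_mass = fmt_num(ind$da_pct_body_mass, 3),
    HR_bpm = fmt_num(ind$hr_bpm, 1))
  utils::write.csv(ind_out, file.path(out_dir, "timeseries.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  tr <- res$trace
  tr_out <- tr
  for (cl in grep("_(prob|degree)$|overall_prob", names(tr_out),
                  value = TRUE)) {
    tr_out[[cl]] <- fmt_num(tr[[cl]], 2)
  }
  tr_out$t_min <- ifelse(is.na(tr$t_min), "", format(tr$t_min))
  utils::write.csv(tr_out, file.path(out_dir, "trace.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  export_fsm(res$fsm, file.path(out_dir, "fsm.json"))
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Built-in case fixtures
#'
#' The two published evaluation scenarios: Case 1, a 25-year-old (177 cm,
#' 68 kg) jogging at 7 km/h for 120 min at 25 degC / 65 % RH in a cotton
#' t-shirt outfit, with strong sweating gains (k_a 250, k_sw 100); Case 2, a
#' 35-year-old (173 cm, 74 kg) running at 12 km/h for 30 min at 28 degC /
#' 50 % RH in a vest outfit, with weak sweating gains (k_a 50, k_sw 10). Body
#' areas use the published explicit values (19199 and 19697 cm^2).
#'
#' @param case 1 or 2.
#' @return a [scenario()].
#' @export
#' @examples
#' case_scenario(1)
case_scenario <- function(case) {
  stopifnot(case %in% c(1, 2))
  path <- system.file("extdata", sprintf("case%d.yaml", case),
                      package = "exertherm", mustWork = TRUE)
  load_scenario(path)
}

#' @rdname case_scenario
#' @export
builtin_fixtures <- function() {
  list(case_scenario(1), case_scenario(2))
}

#' Generate random valid scenarios
#'
#' Seeded scenario generator for property testing. Subjects, environments and
#' exercise plans are drawn from ranges typical of healthy adults on treadmill
#' protocols (age 18-60 y, 3-14 km/h, 15-32 degC, 20-90 % RH, 10-30 min);
#' heart-rate coefficients are jittered within +/-50 % of the two built-in
#' parameter sets and resampled until the saturated loop gain a2 a4/(a1 a3)
#' stays below 0.9. Identical seeds give identical lists.
#'
#' @param seed integer seed.
#' @param n number of scenarios (> 0).
#' @return list of `n` validated [scenario()] objects.
#' @export
#' @examples
#' length(generate_synthetic_scenarios(1, 3))
generate_synthetic_scenarios <- function(seed, n) {
  if (!is.numeric(n) || n < 1) abort_field("n", "must be a positive integer")
  set.seed(seed)
  base_a <- list(c(1.84, 24.32, 0.0636, 0.00321, 8.32, 0.38),
                 c(2.2, 19.96, 0.0831, 0.002526, 8.32, 0.38))
  draw_a <- function() {
    repeat {
      a <- base_a[[sample(2, 1)]] * runif(6, 0.5, 1.5)
      if (a[2] * a[4] / (a[1] * a[3]) < 0.9) return(a)
    }
  }
  lapply(seq_len(n), function(i) {
    a <- draw_a()
    speed <- runif(1, 3, 14)
    scenario(
      subject = subject(age = runif(1, 18, 60),
                        height_cm = runif(1, 150, 195),
                        weight_kg = runif(1, 50, 100),
                        hr_rest = runif(1, 55, 85)),
      environment = environment_conditions(
        air_temperature_c = runif(1, 15, 32),
        relative_humidity = runif(1, 0.2, 0.9)),
      clothing = clothing(material = "cotton",
                          coverage_rate = runif(1, 0.4, 0.8)),
      exercise = exercise_plan(
        exercise_type = if (speed > 8) "running" else "jogging",
        speed_kmh = speed,
        eip = runif(1, 0.4, 0.9),
        duration_min = round(runif(1, 10, 30))),
      params = model_params(k_a = runif(1, 100, 300),
                            k_sw = runif(1, 20, 150),
                            a1 = a[1], a2 = a[2], a3 = a[3],
                            a4 = a[4], a5 = a[5], a6 = a[6]),
      name = sprintf("synthetic-%d", i))
  })
}
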