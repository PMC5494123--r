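# Health-state transition sequencing: fuzzify the simulated indicators at the
# assessment cadence and drive the state machine tick by tick.

#' Run the health-state sequence over simulated physiology
#'
#' Aligns the thermal and heart-rate series at the scenario's assessment
#' cadence, fuzzifies core temperature, dehydration percentage and heart rate
#' at each tick and advances the state machine. The trace starts in state NNN
#' with all probabilities 1 and ends with a closing row (one final
#' unchanged-state probability update, `t_min = NA`) carrying the final
#' state.
#'
#' @param thermal output of [simulate_thermal()].
#' @param heart_rate output of [integrate_hr()].
#' @param sc the [scenario()] that produced both series.
#' @param fsm a [build_fsm()] machine (built fresh by default).
#' @return tibble with columns `t_min`, `state`, `overall_prob`,
#'   `{ct,da,hr}_symptom`, `{ct,da,hr}_degree`, `{ct,da,hr}_prob`; probability
#'   and degree columns are reported rounded half-up to 2 decimals.
#' @export
#' @examples
#' sc <- case_scenario(2)
#' run_scenario(sc)$trace
run_health_sequence <- function(thermal, heart_rate, sc, fsm = build_fsm()) {
  cadence <- sc$params$fsm_cadence
  duration <- sc$exercise$duration_min
  ticks <- seq(0, duration, by = cadence)

  pick <- function(series, times) {
    idx <- match(round(times, 9), round(series$t_min, 9))
    if (anyNA(idx)) {
      abort("thermal/heart-rate series are not aligned with the assessment cadence",
            class = "exertherm_alignment")
    }
    series[idx, ]
  }
  th <- pick(thermal, ticks)
  hr <- pick(heart_rate, ticks)
  sets <- scenario_fuzzy_sets(sc)
  method <- sc$params$overall_update

  n <- length(ticks)
  out <- vector("list", n + 1)
  assess0 <- assess_symptoms(th$t_cr_c[1], th$da_pct[1], hr$hr_bpm[1], sets)
  current <- list(state = "NNN",
                  ind_probs = c(ct = 1, da = 1, hr = 1),
                  overall = 1)
  out[[1]] <- tibble::tibble(
    t_min = 0, state = "NNN", overall_prob = 1,
    ct_symptom = assess0$dominant[["ct"]],
    ct_degree = assess0$dominant_degree[["ct"]], ct_prob = 1,
    da_symptom = assess0$dominant[["da"]],
    da_degree = assess0$dominant_degree[["da"]], da_prob = 1,
    hr_symptom = assess0$dominant[["hr"]],
    hr_degree = assess0$dominant_degree[["hr"]], hr_prob = 1)

  for (i in seq(2, n)) {
    assess <- assess_symptoms(th$t_cr_c[i], th$da_pct[i], hr$hr_bpm[i], sets)
    current <- fsm_step(current, assess, fsm, method = method)
    out[[i]] <- tibble::tibble(
      t_min = ticks[i], state = current$state,
      overall_prob = current$overall,
      ct_symptom = current$dominant[["ct"]],
      ct_degree = current$dominant_degree[["ct"]],
      ct_prob = current$ind_probs[["ct"]],
      da_symptom = current$dominant[["da"]],
      da_degree = current$dominant_degree[["da"]],
      da_prob = current$ind_probs[["da"]],
      hr_symptom = current$dominant[["hr"]],
      hr_degree = current$dominant_degree[["hr"]],
      hr_prob = current$ind_probs[["hr"]])
  }

  # closing row: one more unchanged-state overall update with the final
  # indicator probabilities
  closing_overall <- update_overall_probability(
    current$overall, unname(current$ind_probs), rep(FALSE, 3),
    method = method)
  last <- out[[n]]
  out[[n + 1]] <- dplyr::mutate(last, t_min = NA_real_,
                                overall_prob = closing_overall)

  trace <- dplyr::bind_rows(out)
  num <- c("overall_prob", "ct_degree", "ct_prob", "da_degree", "da_prob",
           "hr_degree", "hr_prob")
  trace[num] <- lapply(trace[num], round_half_up, digits = 2)
  trace
}
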