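# broom-style accessors for run results.

#' Tidy a health simulation
#'
#' Returns the health-state trace joined with the cadence-aligned indicator
#' values, one row per assessment tick (the closing probability row is
#' dropped; it is available in `x$trace`).
#'
#' @param x a `health_sim` from [run_scenario()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.health_sim <- function(x, ...) {
  tr <- dplyr::filter(x$trace, !is.na(.data$t_min))
  dplyr::left_join(tr, x$indicators, by = "t_min")
}

#' Summarise a health simulation in one row
#'
#' @param x a `health_sim` from [run_scenario()].
#' @param ... unused.
#' @return a one-row tibble: final state and probability, number of states
#'   visited, peak core temperature, peak heart rate, total sweat loss and
#'   dehydration percentage, number of warnings.
#' @export
glance.health_sim <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    final_state = s$final_state,
    final_probability = s$final_probability,
    n_states = length(s$states_visited),
    peak_t_cr_c = s$peak_t_cr_c,
    peak_hr_bpm = s$peak_hr_bpm,
    total_da_g = s$total_da_g,
    da_pct_body_mass = s$da_pct_body_mass,
    n_warnings = length(s$warnings))
}

#' @importFrom rlang .data
#' @export
autoplot.health_sim <- function(object, ...) {
  ind <- object$indicators
  sc <- object$scenario
  long <- tidyr::pivot_longer(
    dplyr::select(ind, "t_min", "t_cr_c", "da_pct_body_mass", "hr_bpm"),
    -"t_min", names_to = "indicator", values_to = "value")
  long$indicator <- factor(
    long$indicator,
    levels = c("t_cr_c", "da_pct_body_mass", "hr_bpm"),
    labels = c("Core temperature (degC)", "Dehydration (% body mass)",
               "Heart rate (beats/min)"))
  refs <- tibble::tibble(
    indicator = factor(
      c("Heart rate (beats/min)", "Heart rate (beats/min)"),
      levels = levels(long$indicator)),
    value = c(sc$derived$thr, sc$derived$mhr),
    ref = c("THR", "MHR"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_hline(data = refs,
                        ggplot2::aes(yintercept = .data$value,
                                     linetype = .data$ref),
                        colour = "grey40") +
    ggplot2::facet_wrap(~indicator, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL, linetype = NULL,
                  title = sc$name) +
    ggplot2::theme_minimal()
}
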