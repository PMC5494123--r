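# Shared numerical helpers.

#' Round half away from zero
#'
#' Probabilities in health traces are reported at two decimal places with
#' halves rounded up (0.735 -> 0.74), unlike [base::round()]'s banker's
#' rounding. Values are stored at full precision internally and rounded only
#' for reporting.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.735, 0.625), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Saturated water vapour pressure
#'
#' Antoine-form fit used throughout the two-node literature; input in degrees
#' Celsius, output in mmHg.
#'
#' @param temp_c temperature, degrees C.
#' @return saturation vapour pressure, mmHg.
#' @export
#' @examples
#' svp_mmHg(25) # about 23.76
svp_mmHg <- function(temp_c) {
  exp(18.6686 - 4030.183 / (temp_c + 235))
}

# Field-named validation failure (the field name is the contract: config
# errors must point at the offending entry).
abort_field <- function(field, msg) {
  abort(sprintf("%s: %s", field, msg), class = "exertherm_validation_error")
}

check_range <- function(value, field, min = -Inf, max = Inf,
                        allow_min = TRUE, allow_max = TRUE) {
  if (is.null(value) || length(value) != 1 || !is.numeric(value) ||
      !is.finite(value)) {
    abort_field(field, "must be a single finite number")
  }
  lo_ok <- if (allow_min) value >= min else value > min
  hi_ok <- if (allow_max) value <= max else value < max
  if (!lo_ok || !hi_ok) {
    abort_field(field, sprintf(
      "must be in %s%s, %s%s but is %g",
      if (allow_min) "[" else "(", format(min),
      format(max), if (allow_max) "]" else ")", value))
  }
  invisible(value)
}

divergence_error <- function(time_min, what, value) {
  abort(
    sprintf("simulation diverged at t = %.3f min: %s = %.3f outside physiological bounds",
            time_min, what, value),
    class = "exertherm_divergence")
}
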