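# Nonlinear two-state heart-rate regulation model. The neural state x1 decays
# at rate a1 and is driven by the squared exercise intensity u^2 and by the
# slow peripheral state x2 (thermoregulatory and hormonal after-effects),
# which in turn integrates a sigmoidally gated fraction of x1. The observable
# output is HR = 4 x1 + HR_rest.

#' Sigmoidal peripheral drive
#'
#' `phi(x1) = a4 x1 / (1 + exp(-(x1 - a5)))`: negligible for small `x1`,
#' approaching `a4 x1` once `x1` clears the threshold `a5`.
#'
#' @param x1 neural heart-rate state.
#' @param a4 gain (> 0).
#' @param a5 sigmoid midpoint (> 0).
#' @return drive value.
#' @export
#' @examples
#' phi_sigmoid(24, 0.002526, 8.32) # about 0.0606
phi_sigmoid <- function(x1, a4, a5) {
  a4 * x1 / (1 + exp(-(x1 - a5)))
}

#' Heart-rate model derivatives
#'
#' `dx1/dt = -a1 x1 + a2 x2 + a6 u^2`; `dx2/dt = -a3 x2 + phi(x1)`.
#'
#' @param x1,x2 current states.
#' @param u exercise intensity input (>= 0).
#' @param params a [model_params()] (only `a1`-`a6` are used).
#' @return named numeric vector `c(dx1 = , dx2 = )` per minute.
#' @export
hr_derivatives <- function(x1, x2, u, params) {
  if (u < 0) abort_field("u", "must be non-negative")
  c(dx1 = -params$a1 * x1 + params$a2 * x2 + params$a6 * u^2,
    dx2 = -params$a3 * x2 + phi_sigmoid(x1, params$a4, params$a5))
}

resolve_u_profile <- function(u) {
  if (is.numeric(u) && length(u) == 1) {
    force(u)
    return(function(t) u)
  }
  if (is.data.frame(u)) {
    stopifnot(all(c("t_min", "u") %in% names(u)))
    brk <- u[order(u$t_min), ]
    return(function(t) brk$u[findInterval(t, brk$t_min, left.open = FALSE)])
  }
  if (is.function(u)) return(u)
  abort_field("u", "must be a scalar, a data frame (t_min, u), or a function")
}

#' Integrate the heart-rate model
#'
#' Classical fixed-step fourth-order Runge-Kutta from rest (`x1 = x2 = 0`, so
#' `HR(0) = hr_rest`). The intensity input may be constant or a
#' piecewise-constant profile.
#'
#' @param params a [model_params()].
#' @param u exercise intensity: scalar, data frame with columns `t_min`, `u`
#'   (left-closed steps), or a function of time.
#' @param duration_min total time, minutes.
#' @param dt step, minutes (default 0.05).
#' @param hr_rest resting heart rate, beats/min.
#' @return tibble with `t_min`, `x1`, `x2`, `hr_bpm` (`hr_bpm` is exactly
#'   `4 x1 + hr_rest` at every row).
#' @export
#' @examples
#' p <- model_params(50, 10, 2.2, 19.96, 0.0831, 0.002526, 8.32, 0.38)
#' tail(integrate_hr(p, u = 10, duration_min = 30), 1)
integrate_hr <- function(params, u, duration_min, dt = params$hr_dt,
                         hr_rest = 74) {
  stopifnot(duration_min > 0, dt > 0)
  u_of <- resolve_u_profile(u)
  n <- round(duration_min / dt)
  x1 <- x2 <- numeric(n + 1)
  f <- function(t, y) {
    ut <- u_of(t)
    c(-params$a1 * y[1] + params$a2 * y[2] + params$a6 * ut^2,
      -params$a3 * y[2] + phi_sigmoid(y[1], params$a4, params$a5))
  }
  y <- c(0, 0)
  for (i in seq_len(n)) {
    t0 <- (i - 1) * dt
    k1 <- f(t0, y)
    k2 <- f(t0 + dt / 2, y + dt / 2 * k1)
    k3 <- f(t0 + dt / 2, y + dt / 2 * k2)
    k4 <- f(t0 + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(y))) divergence_error(i * dt, "x1", y[1])
    x1[i + 1] <- y[1]
    x2[i + 1] <- y[2]
  }
  tibble::tibble(t_min = seq(0, by = dt, length.out = n + 1),
                 x1 = x1, x2 = x2, hr_bpm = 4 * x1 + hr_rest)
}

#' Closed-form equilibrium heart rate
#'
#' Analytic steady state of the two-state model: eliminates `x2 = phi(x1)/a3`
#' and solves `0 = -a1 x1 + a2 phi(x1)/a3 + a6 u^2` by bracketed
#' root-finding. Requires the saturated loop gain `a2 a4 / (a1 a3)` below 1,
#' otherwise no bounded equilibrium exists.
#'
#' @param params a [model_params()].
#' @param u constant exercise intensity (>= 0).
#' @param hr_rest resting heart rate, beats/min.
#' @return equilibrium heart rate, beats/min.
#' @export
#' @examples
#' p <- model_params(50, 10, 2.2, 19.96, 0.0831, 0.002526, 8.32, 0.38)
#' equilibrium_hr(p, u = 10) # about 169.4
equilibrium_hr <- function(params, u, hr_rest = 74) {
  if (u < 0) abort_field("u", "must be non-negative")
  gain <- params$a2 * params$a4 / (params$a1 * params$a3)
  if (gain >= 1) {
    abort(sprintf(
      "unstable parameters: saturated loop gain a2*a4/(a1*a3) = %.3f >= 1",
      gain), class = "exertherm_unstable")
  }
  if (u == 0) return(hr_rest + 0) # x1 = 0 is the rest root
  g <- function(x1) {
    -params$a1 * x1 +
      params$a2 * phi_sigmoid(x1, params$a4, params$a5) / params$a3 +
      params$a6 * u^2
  }
  upper <- params$a6 * u^2 / (params$a1 * (1 - gain)) * 2 + 10
  if (g(upper) >= 0) abort("no equilibrium found in bracket",
                           class = "exertherm_unstable")
  x1 <- uniroot(g, c(0, upper), tol = 1e-10)$root
  4 * x1 + hr_rest
}
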