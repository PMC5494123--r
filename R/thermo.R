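# Two-node (core/skin) thermal regulation: heat balance per unit skin area,
# vasomotor-adjusted core-to-skin conductance, sweating and dehydration.
# All fluxes are W/m^2, temperatures degrees C, time minutes.

#' Thermal state at a time point
#'
#' @param t time, minutes.
#' @param t_sk skin temperature, degrees C.
#' @param t_cr core temperature, degrees C.
#' @param s_sk,s_cr heat storage rates of the skin and core node, W/m^2.
#' @param m_rsw regulatory sweat rate, g/min.
#' @param da cumulative dehydration amount, g.
#' @return a list of class `thermal_state`.
#' @export
thermal_state <- function(t = 0, t_sk = 34.1, t_cr = 36.8,
                          s_sk = 0, s_cr = 0, m_rsw = 0, da = 0) {
  structure(list(t = t, t_sk = t_sk, t_cr = t_cr, s_sk = s_sk, s_cr = s_cr,
                 m_rsw = m_rsw, da = da), class = "thermal_state")
}

#' Dry (radiative + convective) heat exchange
#'
#' Combined dry loss from the skin through the clothing,
#' `h (T_sk - T_op) / (1 + 0.155 h I_cl)`, split into radiative and convective
#' parts in proportion to their coefficients. Positive values are heat lost by
#' the skin.
#'
#' @param t_sk skin temperature, degrees C.
#' @param env an [environment_conditions()].
#' @param clo a [clothing()].
#' @param h_c convective heat-transfer coefficient, W/(m^2.K).
#' @param constants a [thermal_constants()].
#' @return named numeric vector `c(R = , C = )`, W/m^2.
#' @export
dry_heat_exchange <- function(t_sk, env, clo, h_c,
                              constants = thermal_constants()) {
  h_r <- constants$h_r
  h <- h_r + h_c
  t_op <- env$air_temperature_c # air == mean radiant here
  total <- h * (t_sk - t_op) / (1 + 0.155 * h * clo$insulation_clo)
  c(R = total * h_r / h, C = total * h_c / h)
}

#' Evaporative heat losses
#'
#' Respiratory loss `0.0023 M (44 - P_a)`; sweat evaporation
#' `lambda m_rsw / A` capped at the biophysical maximum `E_max` set by the
#' skin-air vapour-pressure gradient and clothing permeability; skin diffusion
#' `0.06 (E_max - E_rsw)`.
#'
#' @param t_sk skin temperature, degrees C.
#' @param env an [environment_conditions()].
#' @param clo a [clothing()].
#' @param m_met metabolic rate, W/m^2.
#' @param m_rsw sweat rate, g/min.
#' @param area_cm2 body surface area, cm^2.
#' @param h_c convective coefficient, W/(m^2.K).
#' @param constants a [thermal_constants()].
#' @return named numeric vector `c(E_res = , E_diff = , E_rsw = , E_max = )`,
#'   W/m^2.
#' @export
evaporative_losses <- function(t_sk, env, clo, m_met, m_rsw, area_cm2, h_c,
                               constants = thermal_constants()) {
  p_a <- env$relative_humidity * svp_mmHg(env$air_temperature_c)
  e_res <- max(0.0023 * m_met * (44 - p_a), 0)
  f_cl <- 1 + 0.155 * (constants$h_r + h_c) * clo$insulation_clo
  h_e <- constants$lewis * h_c * clo$evaporative_permeability / f_cl
  e_max <- max(h_e * (svp_mmHg(t_sk) - p_a), 0)
  # 0.68 W.h/g * 60 min/h = 40.8 W per (g/min), spread over the body area
  e_rsw <- min(constants$lambda * 60 * m_rsw / (area_cm2 / 1e4), e_max)
  e_diff <- 0.06 * (e_max - e_rsw)
  c(E_res = e_res, E_diff = e_diff, E_rsw = e_rsw, E_max = e_max)
}

#' Skin blood flow
#'
#' Gagge-style vasomotor control: warm core drives vasodilation, cold skin
#' vasoconstriction; bounded to \[0.5, 90\] L/(m^2.h).
#'
#' @param t_sk,t_cr skin and core temperature, degrees C.
#' @param constants a [thermal_constants()].
#' @return skin blood flow, L/(m^2.h).
#' @export
#' @examples
#' skin_blood_flow(34.1, 36.8) # 6.3 at the set-points
skin_blood_flow <- function(t_sk, t_cr, constants = thermal_constants()) {
  warm_cr <- max(t_cr - constants$t_cr_ini, 0)
  cold_sk <- max(constants$t_sk_ini - t_sk, 0)
  v <- (6.3 + 200 * warm_cr) / (1 + 0.5 * cold_sk)
  min(max(v, 0.5), 90)
}

#' Regulatory sweat rate
#'
#' `m_rsw = scale (k_a dT_cr + k_sw dT_cr dT_sk) A` with warm-signal
#' rectification `dT = max(T - T_ini, 0)`; `A` in cm^2 and `scale` the
#' documented unit-closure constant (`sweat_scale` in [model_params()]).
#'
#' @param t_sk,t_cr skin and core temperature, degrees C.
#' @param params a [model_params()].
#' @param area_cm2 body surface area, cm^2.
#' @param constants a [thermal_constants()].
#' @return sweat rate, g/min (>= 0).
#' @export
sweat_rate <- function(t_sk, t_cr, params, area_cm2,
                       constants = thermal_constants()) {
  d_cr <- max(t_cr - constants$t_cr_ini, 0)
  d_sk <- max(t_sk - constants$t_sk_ini, 0)
  params$sweat_scale * (params$k_a * d_cr + params$k_sw * d_cr * d_sk) *
    area_cm2
}

#' Node heat-storage rates
#'
#' Skin node gains core heat through the vasomotor-adjusted conductance
#' `K_min + c_bl V_bl` and loses the dry and skin-side evaporative fluxes; the
#' core node keeps metabolic heat net of respiration, external work and the
#' core-to-skin transfer. The two rates always sum to the whole-body balance
#' `M - W - R - C - E`.
#'
#' @param fluxes named vector with `R`, `C`, `E_res`, `E_diff`, `E_rsw`
#'   (W/m^2).
#' @param t_sk,t_cr skin and core temperature, degrees C.
#' @param v_bl skin blood flow, L/(m^2.h).
#' @param m_met metabolic rate, W/m^2.
#' @param w_ext external work rate, W/m^2.
#' @param constants a [thermal_constants()].
#' @return named numeric vector `c(S_sk = , S_cr = )`, W/m^2.
#' @export
node_storage_rates <- function(fluxes, t_sk, t_cr, v_bl, m_met, w_ext = 0,
                               constants = thermal_constants()) {
  k_eff <- constants$k_min + constants$c_bl * v_bl
  transfer <- k_eff * (t_cr - t_sk)
  s_sk <- transfer - (fluxes[["R"]] + fluxes[["C"]]) -
    fluxes[["E_diff"]] - fluxes[["E_rsw"]]
  s_cr <- m_met - fluxes[["E_res"]] - w_ext - transfer
  c(S_sk = s_sk, S_cr = s_cr)
}

#' Advance node temperatures one Euler step
#'
#' Explicit Euler update `T += S A dt / (m c)` with the skin/core mass split
#' `m_sk = alpha_sk W`, `m_cr = (1 - alpha_sk) W`. Temperatures outside the
#' physiological simulation bounds (skin 25-45, core 30-45 degrees C) raise a
#' divergence error carrying the offending time.
#'
#' @param state a [thermal_state()].
#' @param rates named vector `c(S_sk, S_cr)`, W/m^2.
#' @param dt step, minutes.
#' @param subj a [subject()].
#' @param constants a [thermal_constants()].
#' @param area_cm2 body surface area, cm^2.
#' @return the advanced [thermal_state()].
#' @export
advance_state <- function(state, rates, dt, subj,
                          constants = thermal_constants(),
                          area_cm2 = body_surface_area(subj)) {
  stopifnot(dt > 0)
  a_m2 <- area_cm2 / 1e4
  m_sk <- constants$alpha_sk * subj$weight_kg
  m_cr <- (1 - constants$alpha_sk) * subj$weight_kg
  # specific heats are W.h/(kg.K); time is minutes, hence the 60
  t_sk <- state$t_sk + rates[["S_sk"]] * a_m2 * dt / (m_sk * constants$c_sk * 60)
  t_cr <- state$t_cr + rates[["S_cr"]] * a_m2 * dt / (m_cr * constants$c_cr * 60)
  t_new <- state$t + dt
  if (t_sk < 25 || t_sk > 45) divergence_error(t_new, "T_sk", t_sk)
  if (t_cr < 30 || t_cr > 45) divergence_error(t_new, "T_cr", t_cr)
  thermal_state(t = t_new, t_sk = t_sk, t_cr = t_cr,
                s_sk = rates[["S_sk"]], s_cr = rates[["S_cr"]],
                m_rsw = state$m_rsw, da = state$da)
}

#' Accumulate dehydration
#'
#' Rectangle-rule accumulation `DA + m_rsw dt`; non-decreasing by
#' construction.
#'
#' @param da dehydration amount so far, g (>= 0).
#' @param m_rsw sweat rate over the step, g/min (>= 0).
#' @param dt step, minutes.
#' @return updated dehydration amount, g.
#' @export
accumulate_dehydration <- function(da, m_rsw, dt) {
  if (da < 0) abort_field("da", "must be non-negative")
  if (m_rsw < 0) abort_field("m_rsw", "must be non-negative")
  da + m_rsw * dt
}

#' Simulate the two-node thermal response of a scenario
#'
#' Fixed-step explicit Euler integration from the set-point temperatures and
#' zero dehydration to the end of the exercise plan. Each step evaluates, in
#' order: dry and evaporative fluxes, skin blood flow, sweat rate, node
#' storage rates, the temperature update and dehydration accumulation.
#'
#' @param sc a [scenario()].
#' @return a tibble with one row per internal step: `t_min`, `t_sk_c`,
#'   `t_cr_c`, `s_sk`, `s_cr`, `v_bl`, `m_rsw_g_min`, `da_g`, `da_pct` (percent
#'   of body mass), `e_rsw`, `e_max`.
#' @export
#' @examples
#' sc <- case_scenario(2)
#' head(simulate_thermal(sc))
simulate_thermal <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  const <- sc$constants
  par <- sc$params
  dt <- par$dt
  area <- sc$derived$area_cm2
  m_met <- sc$derived$metabolic_rate
  w_ext <- sc$exercise$w_ext
  h_c <- sc$derived$h_c
  n <- round(sc$exercise$duration_min / dt)

  t_sk <- t_cr <- s_sk <- s_cr <- v_bl <- m_rsw <- da <- e_rsw <- e_max <-
    numeric(n + 1)
  t_sk[1] <- const$t_sk_ini
  t_cr[1] <- const$t_cr_ini
  state <- thermal_state(t = 0, t_sk = t_sk[1], t_cr = t_cr[1])
  v_bl[1] <- skin_blood_flow(t_sk[1], t_cr[1], const)

  for (i in seq_len(n)) {
    dry <- dry_heat_exchange(state$t_sk, sc$environment, sc$clothing, h_c,
                             const)
    vb <- skin_blood_flow(state$t_sk, state$t_cr, const)
    mr <- sweat_rate(state$t_sk, state$t_cr, par, area, const)
    ev <- evaporative_losses(state$t_sk, sc$environment, sc$clothing, m_met,
                             mr, area, h_c, const)
    rates <- node_storage_rates(c(dry, ev), state$t_sk, state$t_cr, vb,
                                m_met, w_ext, const)
    state$m_rsw <- mr
    state$da <- accumulate_dehydration(state$da, mr, dt)
    state <- advance_state(state, rates, dt, sc$subject, const, area)
    t_sk[i + 1] <- state$t_sk
    t_cr[i + 1] <- state$t_cr
    s_sk[i + 1] <- rates[["S_sk"]]
    s_cr[i + 1] <- rates[["S_cr"]]
    v_bl[i + 1] <- vb
    m_rsw[i + 1] <- mr
    da[i + 1] <- state$da
    e_rsw[i + 1] <- ev[["E_rsw"]]
    e_max[i + 1] <- ev[["E_max"]]
  }
  tibble::tibble(
    t_min = seq(0, by = dt, length.out = n + 1),
    t_sk_c = t_sk, t_cr_c = t_cr, s_sk = s_sk, s_cr = s_cr, v_bl = v_bl,
    m_rsw_g_min = m_rsw, da_g = da,
    da_pct = da / (sc$subject$weight_kg * 1000) * 100,
    e_rsw = e_rsw, e_max = e_max)
}
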