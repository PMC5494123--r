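env25 <- environment_conditions(25, 0.65)
clo_shirt <- clothing("cotton", 0.7)

test_that("dry heat exchange vanishes at zero gradient and shrinks with insulation", {
  r0 <- dry_heat_exchange(25, env25, clo_shirt, h_c = 8)
  expect_equal(unname(r0[["R"]] + r0[["C"]]), 0)
  r1 <- dry_heat_exchange(34, env25, clo_shirt, h_c = 8)
  expect_gt(r1[["R"]] + r1[["C"]], 0)
  thick <- clothing("cotton", 0.7, insulation_clo = 2 * clo_shirt$insulation_clo)
  r2 <- dry_heat_exchange(34, env25, thick, h_c = 8)
  expect_lt(r2[["R"]] + r2[["C"]], r1[["R"]] + r1[["C"]])
})

test_that("evaporative losses respect gradients, proportionality and the E_max cap", {
  # saturated air at skin temperature: no vapour-pressure gradient
  env_sat <- environment_conditions(34, 1)
  ev <- evaporative_losses(34, env_sat, clo_shirt, m_met = 300, m_rsw = 0,
                           area_cm2 = 18000, h_c = 8)
  expect_equal(unname(ev[["E_rsw"]]), 0)
  expect_equal(unname(ev[["E_diff"]]), 0)
  ev0 <- evaporative_losses(34, env25, clo_shirt, m_met = 0, m_rsw = 1,
                            area_cm2 = 18000, h_c = 8)
  expect_equal(unname(ev0[["E_res"]]), 0)
  big <- evaporative_losses(34, env25, clo_shirt, m_met = 300, m_rsw = 1e5,
                            area_cm2 = 18000, h_c = 8)
  expect_equal(unname(big[["E_rsw"]]), unname(big[["E_max"]]))
  expect_true(all(ev >= 0) && all(big >= 0))
})

test_that("skin blood flow implements the vasomotor control law with bounds", {
  expect_equal(skin_blood_flow(34.1, 36.8), 6.3)
  # a 1 K warm core signal saturates the upper bound (206.3 before clamping)
  expect_equal(skin_blood_flow(34.1, 37.8), 90)
  expect_lt(skin_blood_flow(32, 36.8), 6.3)
  expect_gte(skin_blood_flow(20, 30), 0.5)
})

test_that("sweat rate follows the rectified two-signal law", {
  p <- default_hr_params()
  expect_equal(sweat_rate(35, 36.8, p, 19199), 0)
  expect_equal(sweat_rate(33, 36.0, p, 19199), 0)
  only_core <- sweat_rate(34.1, 37.8, p, 19199)
  expect_gt(only_core, 0)
  expect_equal(only_core, p$sweat_scale * p$k_a * 1 * 19199)
  p2 <- default_hr_params()
  p2$k_a <- 2 * p$k_a
  both <- function(pp) sweat_rate(35.1, 37.8, pp, 19199)
  k_a_term <- function(pp) pp$sweat_scale * pp$k_a * 19199
  expect_equal(both(p2) - both(p), k_a_term(p2) - k_a_term(p))
})

test_that("node storage rates conserve the whole-body heat balance", {
  const <- thermal_constants()
  fx0 <- c(R = 0, C = 0, E_res = 0, E_diff = 0, E_rsw = 0)
  r <- node_storage_rates(fx0, 36, 36, v_bl = 6.3, m_met = 0, w_ext = 0)
  expect_equal(unname(r), c(0, 0))
  set.seed(1)
  for (i in 1:100) {
    fx <- c(R = runif(1, -30, 60), C = runif(1, -30, 120),
            E_res = runif(1, 0, 40), E_diff = runif(1, 0, 40),
            E_rsw = runif(1, 0, 300))
    t_sk <- runif(1, 28, 38); t_cr <- runif(1, 35, 41)
    v <- runif(1, 0.5, 90); m <- runif(1, 50, 700); w <- runif(1, 0, 50)
    rr <- node_storage_rates(fx, t_sk, t_cr, v, m, w)
    rhs <- m - w - fx[["R"]] - fx[["C"]] -
      (fx[["E_res"]] + fx[["E_diff"]] + fx[["E_rsw"]])
    expect_equal(unname(rr[["S_sk"]] + rr[["S_cr"]]), unname(rhs),
                 tolerance = 1e-9)
  }
  # raising M by delta raises S_cr by exactly delta
  fx <- c(R = 10, C = 20, E_res = 5, E_diff = 10, E_rsw = 50)
  a <- node_storage_rates(fx, 34, 37, 20, m_met = 300)
  b <- node_storage_rates(fx, 34, 37, 20, m_met = 300 + 7.5)
  expect_equal(b[["S_cr"]] - a[["S_cr"]], 7.5)
  expect_equal(b[["S_sk"]], a[["S_sk"]])
})

test_that("euler state advance respects signs, zero storage and bounds", {
  subj <- subject(30, 175, 70)
  st <- thermal_state(t = 5, t_sk = 34, t_cr = 37)
  same <- advance_state(st, c(S_sk = 0, S_cr = 0), 0.1, subj)
  expect_equal(same$t_sk, 34)
  expect_equal(same$t_cr, 37)
  expect_equal(same$t, 5.1)
  up <- advance_state(st, c(S_sk = 0, S_cr = 100), 0.1, subj)
  expect_gt(up$t_cr, 37)
  expect_error(advance_state(st, c(S_sk = 0, S_cr = 1e7), 1, subj),
               class = "exertherm_divergence")
})

test_that("dehydration accumulates by the rectangle rule and never decreases", {
  expect_equal(accumulate_dehydration(0, 0, 1), 0)
  da <- 0
  for (i in 1:10) da <- accumulate_dehydration(da, 5, 1)
  expect_equal(da, 50)
  expect_error(accumulate_dehydration(-1, 5, 1), "da")
  expect_error(accumulate_dehydration(0, -5, 1), "m_rsw")
  th <- simulate_thermal(short_scenario())
  expect_true(all(diff(th$da_g) >= 0))
})

test_that("a resting subject in a neutral environment stays at the set-point", {
  th <- simulate_thermal(neutral_rest_scenario())
  expect_true(all(abs(th$t_cr_c - 36.8) <= 0.3))
})

test_that("no sweat is produced while the core has never exceeded its set-point", {
  p <- default_hr_params()
  set.seed(4)
  for (i in 1:50) {
    expect_equal(sweat_rate(runif(1, 30, 40), runif(1, 33, 36.8), p, 19199),
                 0)
  }
  th <- simulate_thermal(case_scenario(2))
  expect_equal(max(th$da_g[cummax(th$t_cr_c) <= 36.8]), 0)
  # the warm core signal is what switches sweating on
  expect_gt(max(th$da_g), 0)
})

test_that("the long jogging case plateaus near 38.8 degC and dehydrates mildly", {
  th <- simulate_thermal(case_scenario(1))
  plateau <- th$t_cr_c[th$t_min >= 30]
  expect_true(all(plateau >= 38.3 & plateau <= 39.3))
  # mild dehydration (>= 1 % of body mass) is reached before the end
  expect_lt(th$t_min[which(th$da_pct >= 1)[1]], 120)
  expect_true(all(diff(th$da_g) >= 0))
})

test_that("the fast running case heats faster than the jogging case", {
  th1 <- simulate_thermal(case_scenario(1))
  th2 <- simulate_thermal(case_scenario(2))
  shared <- intersect(round(th1$t_min, 6), round(th2$t_min, 6))
  a <- th1$t_cr_c[match(shared, round(th1$t_min, 6))]
  b <- th2$t_cr_c[match(shared, round(th2$t_min, 6))]
  expect_true(all(b[-1] >= a[-1]))
  expect_gt(max(b), max(a[th1$t_min <= 30]))
  expect_gt(max(b), 39.6) # reaches the high-temperature plateau
})

test_that("halving the integration step barely moves the final core temperature", {
  sc <- case_scenario(1)
  coarse <- simulate_thermal(sc)
  sc$params$dt <- 0.05
  fine <- simulate_thermal(sc)
  expect_lt(abs(tail(coarse$t_cr_c, 1) - tail(fine$t_cr_c, 1)), 0.02)
})

test_that("warmer environments give (near-)pointwise warmer core traces", {
  scs <- generate_synthetic_scenarios(7, 2)
  for (s in scs) {
    s_warm <- s
    s_warm$environment$air_temperature_c <-
      s$environment$air_temperature_c + 5
    a <- simulate_thermal(s)
    b <- simulate_thermal(s_warm)
    # tolerance covers a millikelvin-scale early transient introduced by the
    # core x skin sweating cross term
    expect_true(all(b$t_cr_c >= a$t_cr_c - 0.01))
    expect_gt(tail(b$t_cr_c, 1), tail(a$t_cr_c, 1))
  }
})
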