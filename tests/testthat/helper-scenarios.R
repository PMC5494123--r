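# Scenario builders shared across tests.

default_hr_params <- function(...) {
  model_params(k_a = 250, k_sw = 100,
               a1 = 1.84, a2 = 24.32, a3 = 0.0636, a4 = 0.00321,
               a5 = 8.32, a6 = 0.38, ...)
}

case2_hr_params <- function(...) {
  model_params(k_a = 50, k_sw = 10,
               a1 = 2.2, a2 = 19.96, a3 = 0.0831, a4 = 0.002526,
               a5 = 8.32, a6 = 0.38, ...)
}

# thermoneutral resting scenario: metabolic rate clamped to 1 MET
neutral_rest_scenario <- function(duration_min = 60) {
  scenario(
    subject(30, 175, 70),
    environment_conditions(27, 0.4),
    clothing("cotton", 0.7),
    exercise_plan("rest", speed_kmh = 0, eip = 0.5,
                  duration_min = duration_min,
                  metabolic_rate_override = 58.2),
    default_hr_params(),
    name = "neutral-rest")
}

# short moderate scenario for fast end-to-end tests
short_scenario <- function(duration_min = 10, fsm_cadence = 1) {
  scenario(
    subject(30, 175, 70),
    environment_conditions(24, 0.5),
    clothing("cotton", 0.6),
    exercise_plan("jogging", speed_kmh = 8, eip = 0.6,
                  duration_min = duration_min),
    default_hr_params(fsm_cadence = fsm_cadence),
    name = "short")
}

# draw random stable heart-rate parameter sets around the built-in ones
random_stable_params <- function(n, seed) {
  set.seed(seed)
  base <- c(1.84, 24.32, 0.0636, 0.00321, 8.32, 0.38)
  lapply(seq_len(n), function(i) {
    repeat {
      a <- base * runif(6, 0.5, 1.5)
      if (a[2] * a[4] / (a[1] * a[3]) < 0.9) break
    }
    model_params(100, 10, a[1], a[2], a[3], a[4], a[5], a[6])
  })
}

scenario_from_yaml_roundtrip <- function(sc) {
  f <- tempfile(fileext = ".yaml")
  write_scenario(sc, f)
  load_scenario(f)
}
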