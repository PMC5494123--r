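Package: exertherm
Title: Exercise Thermophysiology Simulation and Fuzzy Health-State
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates human thermal and cardiovascular responses to
    treadmill exercise with a two-node (core/skin) thermoregulation model
    coupled to a nonlinear two-state heart-rate regulation model, and
    converts the simulated core temperature, dehydration and heart rate
    into a probabilistic sequence of health states with a fuzzy finite
    state machine. Provides scenario configuration files, trapezoidal
    fuzzification of physiological indicators, health-state transition
    probability updates, built-in case fixtures, a seeded synthetic
    scenario generator, tidy accessors and ggplot2 visualisations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
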