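# Scenario records: subject, environment, clothing, exercise plan and model
# parameters, with the derived quantities (body surface area, MHR, THR,
# metabolic rate) every downstream model consumes.

#' Subject description
#'
#' @param age age in years (> 0).
#' @param height_cm standing height, cm.
#' @param weight_kg body mass, kg.
#' @param hr_rest resting heart rate, beats/min (default 74).
#' @param body_area_cm2 optional explicit body surface area, cm^2. When
#'   supplied it overrides the Du Bois estimate from height and weight.
#' @return a validated list of class `exertherm_subject`.
#' @export
#' @examples
#' subject(25, 177, 68)
subject <- function(age, height_cm, weight_kg, hr_rest = 74,
                    body_area_cm2 = NULL) {
  check_range(age, "age", 0, 130, allow_min = FALSE)
  check_range(height_cm, "height", 0, 300, allow_min = FALSE)
  check_range(weight_kg, "weight", 0, 400, allow_min = FALSE)
  check_range(hr_rest, "hr_rest", 30, 120)
  if (!is.null(body_area_cm2)) {
    check_range(body_area_cm2, "body_area_cm2", 0, Inf, allow_min = FALSE)
  }
  structure(list(age = age, height_cm = height_cm, weight_kg = weight_kg,
                 hr_rest = hr_rest, body_area_cm2 = body_area_cm2),
            class = "exertherm_subject")
}

#' Environment conditions
#'
#' @param air_temperature_c ambient (and mean radiant) temperature, degrees C.
#' @param relative_humidity relative humidity as a fraction in \[0, 1\].
#' @return a validated list of class `exertherm_environment`.
#' @export
environment_conditions <- function(air_temperature_c, relative_humidity) {
  check_range(air_temperature_c, "air_temperature", -40, 60)
  check_range(relative_humidity, "relative_humidity", 0, 1)
  structure(list(air_temperature_c = air_temperature_c,
                 relative_humidity = relative_humidity),
            class = "exertherm_environment")
}

# Lumped clothing lookup: intrinsic insulation of the fully covering garment
# (clo) and the factor by which coverage blocks evaporation. A cotton t-shirt
# and shorts outfit (70 % coverage) maps to about 0.30 clo, a vest and shorts
# (50 %) to about 0.22 clo.
.clothing_base <- c(cotton = 0.43, synthetic = 0.37, wool = 0.60, none = 0)

#' Clothing description
#'
#' Garment-level heat and moisture transport is reduced to a lumped thermal
#' insulation (clo) and an evaporative permeability fraction, derived from the
#' material and coverage rate unless given explicitly.
#'
#' @param material garment material label; one of `"cotton"`, `"synthetic"`,
#'   `"wool"`, `"none"`.
#' @param coverage_rate fraction of body surface covered, in \[0, 1\].
#' @param insulation_clo optional explicit insulation, clo (1 clo =
#'   0.155 m^2.K/W).
#' @param evaporative_permeability optional explicit fraction in \[0, 1\] of
#'   the maximal evaporative flux the ensemble lets through.
#' @return a validated list of class `exertherm_clothing`.
#' @export
clothing <- function(material = "cotton", coverage_rate = 0.7,
                     insulation_clo = NULL, evaporative_permeability = NULL) {
  check_range(coverage_rate, "coverage_rate", 0, 1)
  if (!material %in% names(.clothing_base)) {
    abort_field("material",
                paste("must be one of:", toString(names(.clothing_base))))
  }
  if (is.null(insulation_clo)) {
    insulation_clo <- unname(.clothing_base[material]) * coverage_rate
  }
  check_range(insulation_clo, "insulation", 0, 4)
  if (is.null(evaporative_permeability)) {
    evaporative_permeability <- 1 - 0.15 * coverage_rate
  }
  check_range(evaporative_permeability, "evaporative_permeability", 0, 1)
  structure(list(material = material, coverage_rate = coverage_rate,
                 insulation_clo = insulation_clo,
                 evaporative_permeability = evaporative_permeability),
            class = "exertherm_clothing")
}

#' Exercise plan
#'
#' @param exercise_type free label ("jogging", "running", ...).
#' @param speed_kmh treadmill speed, km/h (>= 0).
#' @param eip exercise intensity percentage, fraction in (0, 1]; positions the
#'   target heart rate between rest and maximum.
#' @param duration_min exercise duration, minutes (> 0).
#' @param u optional explicit intensity input of the heart-rate model
#'   (dimensionless). Defaults to `speed_kmh * u_scale`.
#' @param u_scale scale applied to speed when `u` is not given (default 1).
#' @param metabolic_rate_override optional metabolic rate, W/m^2, replacing
#'   the speed-based mapping.
#' @param w_ext external mechanical work rate, W/m^2 (default 0 for level
#'   treadmill locomotion).
#' @return a validated list of class `exertherm_exercise`.
#' @export
exercise_plan <- function(exercise_type = "jogging", speed_kmh, eip,
                          duration_min, u = NULL, u_scale = 1,
                          metabolic_rate_override = NULL, w_ext = 0) {
  check_range(speed_kmh, "speed", 0, 40)
  check_range(eip, "eip", 0, 1, allow_min = FALSE)
  check_range(duration_min, "duration", 0, Inf, allow_min = FALSE)
  check_range(u_scale, "u_scale", 0, Inf)
  if (!is.null(u)) check_range(u, "u", 0, Inf)
  if (!is.null(metabolic_rate_override)) {
    check_range(metabolic_rate_override, "metabolic_rate_override", 0, Inf,
                allow_min = FALSE)
  }
  check_range(w_ext, "w_ext", 0, Inf)
  structure(list(exercise_type = exercise_type, speed_kmh = speed_kmh,
                 eip = eip, duration_min = duration_min, u = u,
                 u_scale = u_scale,
                 metabolic_rate_override = metabolic_rate_override,
                 w_ext = w_ext),
            class = "exertherm_exercise")
}

#' Model parameters
#'
#' Subject-specific coefficients of the sweating model and the heart-rate
#' regulation model, plus the numerical settings of a run.
#'
#' @param k_a sweat gain on the warm core signal (>= 0).
#' @param k_sw sweat gain on the core x skin cross term (>= 0).
#' @param a1,a2,a3,a4,a5,a6 positive coefficients of the two-state heart-rate
#'   model; `a1`/`a3` are the decay rates of the neural and peripheral states,
#'   `a2` couples the peripheral state back into the neural one, `a4`/`a5`
#'   shape the sigmoidal peripheral drive and `a6` scales the squared exercise
#'   intensity input.
#' @param dt thermal integration step, minutes.
#' @param hr_dt heart-rate model integration step, minutes.
#' @param fsm_cadence assessment/reporting interval of the health predictor,
#'   minutes; must be a multiple of `dt`.
#' @param sweat_scale unit-closure constant of the sweating model, grams per
#'   minute produced per (unit control signal x cm^2 body area). Calibrated
#'   default 3.8e-7; see the methods vignette.
#' @param overall_update `"mean"` (default; mean over the three indicators of
#'   per-indicator contributions, the reading that reproduces the worked
#'   probability tables) or `"printed"` (the literal 1/(N+1) + 1/M form).
#' @return a validated list of class `exertherm_params`.
#' @export
model_params <- function(k_a, k_sw, a1, a2, a3, a4, a5, a6,
                         dt = 0.1, hr_dt = 0.05, fsm_cadence = 1,
                         sweat_scale = 3.8e-7,
                         overall_update = c("mean", "printed")) {
  check_range(k_a, "k_a", 0, Inf)
  check_range(k_sw, "k_sw", 0, Inf)
  a <- c(a1, a2, a3, a4, a5, a6)
  for (i in seq_along(a)) {
    check_range(a[[i]], paste0("a", i), 0, Inf, allow_min = FALSE)
  }
  check_range(dt, "dt", 0, Inf, allow_min = FALSE)
  check_range(hr_dt, "hr_dt", 0, Inf, allow_min = FALSE)
  check_range(fsm_cadence, "fsm_cadence", dt, Inf)
  if (abs(fsm_cadence / dt - round(fsm_cadence / dt)) > 1e-8) {
    abort_field("fsm_cadence", "must be an integer multiple of dt")
  }
  check_range(sweat_scale, "sweat_scale", 0, Inf)
  overall_update <- match.arg(overall_update)
  structure(list(k_a = k_a, k_sw = k_sw,
                 a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6,
                 dt = dt, hr_dt = hr_dt, fsm_cadence = fsm_cadence,
                 sweat_scale = sweat_scale, overall_update = overall_update),
            class = "exertherm_params")
}

#' Physical constants of the two-node thermal model
#'
#' Defaults follow the standard two-node (core/skin) formulation: minimum
#' tissue conductance, specific heat of blood, the 10 % skin mass fraction and
#' thermoneutral set-point temperatures.
#'
#' @param k_min minimum heat conductance of skin tissue, W/(m^2.K).
#' @param c_bl specific heat of blood, W.h/(L.K).
#' @param alpha_sk skin fraction of body mass, in (0, 1).
#' @param c_sk,c_cr specific heat of skin and core tissue, W.h/(kg.K).
#' @param t_sk_ini,t_cr_ini set-point (initial) skin and core temperatures,
#'   degrees C.
#' @param h_r linear radiative heat transfer coefficient, W/(m^2.K).
#' @param lewis Lewis relation, degC/mmHg; multiplies the convective
#'   coefficient to give the evaporative one.
#' @param lambda latent heat of sweat, W.h/g.
#' @return a list of class `exertherm_constants`.
#' @export
thermal_constants <- function(k_min = 5.28, c_bl = 1.163, alpha_sk = 0.1,
                              c_sk = 0.97, c_cr = 0.97,
                              t_sk_ini = 34.1, t_cr_ini = 36.8,
                              h_r = 4.7, lewis = 2.2, lambda = 0.68) {
  for (f in c("k_min", "c_bl", "c_sk", "c_cr", "h_r", "lewis", "lambda")) {
    check_range(get(f), f, 0, Inf, allow_min = FALSE)
  }
  check_range(alpha_sk, "alpha_sk", 0, 1, allow_min = FALSE, allow_max = FALSE)
  check_range(t_sk_ini, "t_sk_ini", 25, 40)
  check_range(t_cr_ini, "t_cr_ini", 30, 42)
  structure(list(k_min = k_min, c_bl = c_bl, alpha_sk = alpha_sk,
                 c_sk = c_sk, c_cr = c_cr, t_sk_ini = t_sk_ini,
                 t_cr_ini = t_cr_ini, h_r = h_r, lewis = lewis,
                 lambda = lambda),
            class = "exertherm_constants")
}

#' Body surface area
#'
#' Returns the explicit `body_area_cm2` override when the subject carries one,
#' otherwise the Du Bois estimate 0.007184 W^0.425 H^0.725 (m^2) converted to
#' cm^2.
#'
#' @param subj a [subject()].
#' @return body surface area in cm^2.
#' @export
#' @examples
#' body_surface_area(subject(25, 177, 68)) # about 18415
body_surface_area <- function(subj) {
  if (!is.null(subj$body_area_cm2)) return(subj$body_area_cm2)
  0.007184 * subj$weight_kg^0.425 * subj$height_cm^0.725 * 1e4
}

#' Maximum heart rate
#'
#' Age-dependent quadratic MHR = 163 + 1.16 age - 0.018 age^2 (beats/min).
#'
#' @param age age in years (> 0).
#' @return maximum tolerable heart rate, beats/min.
#' @export
#' @examples
#' max_heart_rate(35) # 181.55
max_heart_rate <- function(age) {
  check_range(age, "age", 0, Inf)
  163 + 1.16 * age - 0.018 * age^2
}

#' Target heart rate
#'
#' Karvonen-style interpolation THR = (MHR - HR_rest) EIP + HR_rest.
#'
#' @param mhr maximum heart rate, beats/min; must exceed `hr_rest`.
#' @param eip exercise intensity percentage, fraction in \[0, 1\].
#' @param hr_rest resting heart rate, beats/min.
#' @return target heart rate, beats/min.
#' @export
#' @examples
#' target_heart_rate(181.55, 0.8, 74) # 160.04
target_heart_rate <- function(mhr, eip, hr_rest = 74) {
  check_range(eip, "eip", 0, 1)
  if (!is.numeric(mhr) || mhr <= hr_rest) {
    abort_field("mhr", "must exceed hr_rest")
  }
  (mhr - hr_rest) * eip + hr_rest
}

# Effective treadmill heat-load table (km/h -> MET). Below 6 km/h these are
# the ACSM walking-equation values; the jog/run anchors are calibrated so the
# two built-in cases reproduce their published core-temperature trajectories
# (see the methods vignette). Linearly interpolated, linearly extrapolated
# above the last anchor; strictly increasing in speed.
.met_anchors <- list(
  speed = c(0, 3, 5, 6, 7, 9, 12, 16),
  met   = c(1, 2.43, 3.38, 3.86, 5.25, 5.85, 6.71, 7.8))

#' Metabolic rate from treadmill speed
#'
#' Monotone piecewise-linear mapping from treadmill speed to areal metabolic
#' heat production, via an effective MET table (1 MET = 58.2 W/m^2). An
#' explicit `metabolic_rate_override` on the plan wins.
#'
#' @param plan an [exercise_plan()].
#' @param subj a [subject()] (reserved for subject-specific mappings).
#' @return metabolic rate, W/m^2.
#' @export
#' @examples
#' metabolic_rate(exercise_plan(speed_kmh = 0, eip = 0.5, duration_min = 10))
metabolic_rate <- function(plan, subj = NULL) {
  if (!is.null(plan$metabolic_rate_override)) {
    return(plan$metabolic_rate_override)
  }
  s <- plan$speed_kmh
  if (s < 0) abort_field("speed", "must be non-negative")
  anc <- .met_anchors
  n <- length(anc$speed)
  met <- if (s >= anc$speed[n]) {
    slope <- 0.27
    anc$met[n] + slope * (s - anc$speed[n])
  } else {
    approx(anc$speed, anc$met, xout = s)$y
  }
  met * 58.2
}

# Nishi-Gagge activity-generated convective coefficient for treadmill
# locomotion (limb movement at near-zero bulk air speed), floored at the
# still-air value.
convective_coefficient <- function(speed_kmh) {
  v <- speed_kmh / 3.6
  max(3, 6.51 * v^0.391)
}

resolve_u <- function(plan) {
  plan$u %||% (plan$speed_kmh * plan$u_scale)
}

#' Assemble a scenario
#'
#' Bundles subject, environment, clothing, exercise plan and model parameters
#' and populates the derived quantities (body surface area, MHR, THR,
#' metabolic rate, heart-rate drive `u`, convective coefficient).
#'
#' @param subject a [subject()].
#' @param environment an [environment_conditions()].
#' @param clothing a [clothing()].
#' @param exercise an [exercise_plan()].
#' @param params a [model_params()].
#' @param constants a [thermal_constants()].
#' @param fuzzy_sets optional fuzzy-set breakpoint table overriding
#'   [default_fuzzy_sets()]; same columns.
#' @param name optional scenario label.
#' @return a list of class `scenario` with a `derived` component.
#' @export
scenario <- function(subject, environment, clothing, exercise, params,
                     constants = thermal_constants(), fuzzy_sets = NULL,
                     name = "scenario") {
  stopifnot(inherits(subject, "exertherm_subject"),
            inherits(environment, "exertherm_environment"),
            inherits(clothing, "exertherm_clothing"),
            inherits(exercise, "exertherm_exercise"),
            inherits(params, "exertherm_params"),
            inherits(constants, "exertherm_constants"))
  mhr <- max_heart_rate(subject$age)
  derived <- list(
    area_cm2 = body_surface_area(subject),
    mhr = mhr,
    thr = target_heart_rate(mhr, exercise$eip, subject$hr_rest),
    metabolic_rate = metabolic_rate(exercise, subject),
    u = resolve_u(exercise),
    h_c = convective_coefficient(exercise$speed_kmh))
  structure(list(name = name, subject = subject, environment = environment,
                 clothing = clothing, exercise = exercise, params = params,
                 constants = constants, fuzzy_sets = fuzzy_sets,
                 derived = derived),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s\n", x$name))
  cat(sprintf("  subject: %g y, %g cm, %g kg (A = %.0f cm^2, HR_rest = %g)\n",
              x$subject$age, x$subject$height_cm, x$subject$weight_kg,
              x$derived$area_cm2, x$subject$hr_rest))
  cat(sprintf("  environment: %.1f degC, %.0f%% RH\n",
              x$environment$air_temperature_c,
              100 * x$environment$relative_humidity))
  cat(sprintf("  clothing: %s, coverage %.0f%% (%.2f clo)\n",
              x$clothing$material, 100 * x$clothing$coverage_rate,
              x$clothing$insulation_clo))
  cat(sprintf("  exercise: %s %g km/h, EIP %.0f%%, %g min (u = %g, M = %.1f W/m^2)\n",
              x$exercise$exercise_type, x$exercise$speed_kmh,
              100 * x$exercise$eip, x$exercise$duration_min, x$derived$u,
              x$derived$metabolic_rate))
  cat(sprintf("  MHR = %.2f, THR = %.2f beats/min\n",
              x$derived$mhr, x$derived$thr))
  invisible(x)
}

scenario_from_list <- function(doc) {
  need <- function(section, field, where = doc) {
    val <- where[[section]][[field]]
    if (is.null(val)) abort_field(field, sprintf("missing from '%s'", section))
    val
  }
  opt <- function(section, field, default = NULL) {
    doc[[section]][[field]] %||% default
  }
  subj <- subject(
    age = need("subject", "age"),
    height_cm = need("subject", "height_cm"),
    weight_kg = need("subject", "weight_kg"),
    hr_rest = opt("subject", "hr_rest", 74),
    body_area_cm2 = opt("subject", "body_area_cm2"))
  env <- environment_conditions(
    air_temperature_c = need("environment", "air_temperature_c"),
    relative_humidity = need("environment", "relative_humidity"))
  clo <- clothing(
    material = opt("clothing", "material", "cotton"),
    coverage_rate = opt("clothing", "coverage_rate", 0.7),
    insulation_clo = opt("clothing", "insulation_clo"),
    evaporative_permeability = opt("clothing", "evaporative_permeability"))
  exe <- exercise_plan(
    exercise_type = opt("exercise", "exercise_type", "jogging"),
    speed_kmh = need("exercise", "speed_kmh"),
    eip = need("exercise", "eip"),
    duration_min = need("exercise", "duration_min"),
    u = opt("exercise", "u"),
    u_scale = opt("exercise", "u_scale", 1),
    metabolic_rate_override = opt("exercise", "metabolic_rate_override"),
    w_ext = opt("exercise", "w_ext", 0))
  par_doc <- doc$parameters
  if (is.null(par_doc)) abort_field("parameters", "section missing")
  par <- model_params(
    k_a = need("parameters", "k_a"), k_sw = need("parameters", "k_sw"),
    a1 = need("parameters", "a1"), a2 = need("parameters", "a2"),
    a3 = need("parameters", "a3"), a4 = need("parameters", "a4"),
    a5 = need("parameters", "a5"), a6 = need("parameters", "a6"),
    dt = opt("parameters", "dt", 0.1),
    hr_dt = opt("parameters", "hr_dt", 0.05),
    fsm_cadence = opt("parameters", "fsm_cadence", 1),
    sweat_scale = opt("parameters", "sweat_scale", 3.8e-7),
    overall_update = opt("parameters", "overall_update", "mean"))
  const_doc <- doc$constants %||% list()
  const <- do.call(thermal_constants, const_doc)
  fz <- if (!is.null(doc$fuzzy_sets)) {
    dplyr::bind_rows(lapply(doc$fuzzy_sets, tibble::as_tibble))
  }
  scenario(subj, env, clo, exe, par, const, fuzzy_sets = fz,
           name = doc$name %||% "scenario")
}

#' Load a scenario from a YAML or JSON config file
#'
#' Missing required fields and out-of-range values raise an error naming the
#' offending field.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` scenario document.
#' @return a validated [scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such scenario file: %s", path))
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  scenario_from_list(doc)
}

scenario_to_list <- function(sc) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  out <- list(name = sc$name,
              subject = strip(sc$subject),
              environment = strip(sc$environment),
              clothing = strip(sc$clothing),
              exercise = strip(sc$exercise),
              parameters = strip(sc$params),
              constants = strip(sc$constants))
  if (!is.null(sc$fuzzy_sets)) {
    out$fuzzy_sets <- lapply(seq_len(nrow(sc$fuzzy_sets)),
                             function(i) as.list(sc$fuzzy_sets[i, ]))
  }
  out
}

#' Serialise a scenario back to YAML or JSON
#'
#' Writes the input fields (not the derived quantities) so that
#' `load_scenario(write_scenario(sc, f))` round-trips to an identical
#' scenario.
#'
#' @param sc a [scenario()].
#' @param path destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  doc <- scenario_to_list(sc)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
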