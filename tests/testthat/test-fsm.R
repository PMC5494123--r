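fsm <- build_fsm()

test_that("the machine enumerates 12 symptoms and 18 states exactly", {
  expect_equal(nrow(fsm$symptoms), 12)
  expect_equal(nrow(fsm$states), 18)
  # brute-force enumeration oracle
  oracle <- apply(expand.grid(c("H", "N", "F"), c("N", "D"),
                              c("B", "N", "T")), 1, paste0, collapse = "")
  expect_setequal(fsm$states$code, oracle)
  expect_equal(nrow(fsm$transitions), 18 * 12)
  expect_true(all(fsm$transitions$weight == 1))
})

test_that("each symptom rewrites only its own indicator letter", {
  expect_equal(fsm_transition(fsm, "NNN", "hhr"), "NNT")
  expect_equal(fsm_transition(fsm, "NNN", "sht"), "FNN")
  expect_equal(fsm_transition(fsm, "FNT", "mid"), "FDT")
  expect_equal(fsm_transition(fsm, "FNT", "nt"), "NNT")
  pos <- c(ct = 1, da = 2, hr = 3)
  meta <- fsm$symptoms[match(fsm$transitions$symptom, fsm$symptoms$symptom), ]
  for (i in seq_len(nrow(fsm$transitions))) {
    from <- fsm$transitions$from[i]
    to <- fsm$transitions$to[i]
    p <- pos[meta$indicator[i]]
    expect_equal(substr(to, p, p), meta$letter[i])
    # all other letters untouched
    others <- setdiff(1:3, p)
    expect_equal(substring(to, others, others), substring(from, others, others))
  }
})

test_that("syndrome annotations follow the clinical letter semantics", {
  syn <- setNames(fsm$states$syndromes, fsm$states$code)
  expect_equal(syn[["NNN"]], "Normal")
  expect_equal(syn[["NNB"]], "Bradycardia")
  expect_equal(syn[["NNT"]], "Tachycardia")
  hypo <- grepl("^H", names(syn))
  expect_true(all(grepl("Hypothermia", syn[hypo])))
  hyper <- grepl("^F", names(syn))
  expect_true(all(grepl("Hyperthermia", syn[hyper])))
  dehydrated <- substr(names(syn), 2, 2) == "D" & names(syn) != "FDT"
  expect_true(all(grepl("[Dd]ehydration", syn[dehydrated])))
  expect_true(grepl("shock", syn[["FDT"]]))
  expect_true(all(grepl("heatstroke", syn[grepl("^FD", names(syn))])))
  arr <- substr(names(syn), 3, 3) %in% c("B", "T") &
    !names(syn) %in% c("NNB", "NNT")
  expect_true(all(grepl("arrhythmia", syn[arr])))
})

test_that("transition probability is the max-min composition over the symptom set", {
  deg <- c(lt = 0, nt = 0, sht = 1, mht = 0, ht = 0)
  expect_equal(transition_probability(deg, "ct", fsm, "NNN"), 1)
  deg2 <- c(lt = 0, nt = 0, sht = 0.4, mht = 0.56, ht = 0)
  expect_equal(transition_probability(deg2, "ct", fsm, "NNN"), 0.56)
  # a low transition weight caps a high degree
  w <- tibble::tibble(from = "NNN", symptom = "mht", weight = 0.3)
  fsm_w <- build_fsm(weights = w)
  deg3 <- c(lt = 0, nt = 0, sht = 0, mht = 0.9, ht = 0)
  expect_equal(transition_probability(deg3, "ct", fsm_w, "NNN"), 0.3)
  expect_error(transition_probability(c(x = 1), "ct", fsm), "assessment")
})

test_that("indicator probability updates average with the (complemented) prior", {
  expect_equal(update_indicator_probability(1, 1, changed = FALSE), 1)
  expect_equal(update_indicator_probability(0.5, 1, changed = FALSE), 0.75)
  expect_equal(update_indicator_probability(0.8, 0.9, changed = TRUE), 0.55)
  expect_error(update_indicator_probability(1.2, 1, FALSE), "prev")
  expect_error(update_indicator_probability(0.5, -0.1, FALSE), "trans")
})

test_that("overall probability reproduces the published worked rows", {
  none <- rep(FALSE, 3)
  expect_equal(update_overall_probability(1, c(0.7, 1, 1), none), 0.95)
  expect_equal(update_overall_probability(0.96, c(1, 1, 1), none), 0.98)
  expect_equal(update_overall_probability(0.62, c(1, 0.55, 1), none), 0.735)
  # unchanged state with unit indicator probabilities converges to 1 as
  # mu(n) = (mu(n-1) + 1) / 2 -- the published 0.68 -> 0.98 chain
  mu <- 0.68
  chain <- c()
  for (i in 1:4) {
    mu <- update_overall_probability(mu, c(1, 1, 1), none)
    chain <- c(chain, round_half_up(mu, 2))
  }
  expect_equal(chain, c(0.84, 0.92, 0.96, 0.98))
  expect_true(all(diff(c(0.68, chain)) > 0))
})

test_that("the printed overall-update variant stays in range and differs as documented", {
  none <- rep(FALSE, 3)
  v <- update_overall_probability(1, c(0.7, 1, 1), none, method = "printed")
  expect_true(v >= 0 && v <= 1)
  expect_false(isTRUE(all.equal(v, 0.95)))
  ch <- c(TRUE, FALSE, FALSE)
  v2 <- update_overall_probability(0.9, c(0.8, 1, 1), ch, method = "printed")
  expect_true(v2 >= 0 && v2 <= 1)
})

test_that("one machine tick combines dominant symptoms into the next state", {
  sets <- default_fuzzy_sets(160.04, 181.55)
  current <- list(state = "NNN", ind_probs = c(ct = 1, da = 1, hr = 1),
                  overall = 1)
  still <- fsm_step(current, assess_symptoms(36.8, 0, 74, sets), fsm)
  expect_equal(still$state, "NNN")
  expect_equal(unname(still$ind_probs), c(1, 1, 1))
  expect_equal(still$overall, 1)

  warm <- fsm_step(current, assess_symptoms(37.7, 0, 74, sets), fsm)
  expect_equal(warm$state, "FNN")
  expect_equal(unname(warm$changed), c(TRUE, FALSE, FALSE))

  cur2 <- list(state = "FNT", ind_probs = c(ct = 1, da = 0.9, hr = 1),
               overall = 0.85)
  hot <- fsm_step(cur2, assess_symptoms(38.8, 1.4, 175, sets), fsm)
  expect_equal(hot$state, "FDT")
})

test_that("health sequences are deterministic and bounded", {
  sc <- short_scenario()
  th <- simulate_thermal(sc)
  hr <- integrate_hr(sc$params, sc$derived$u, sc$exercise$duration_min,
                     hr_rest = sc$subject$hr_rest)
  t1 <- run_health_sequence(th, hr, sc)
  t2 <- run_health_sequence(th, hr, sc)
  expect_identical(t1, t2)
  probs <- unlist(t1[, c("overall_prob", "ct_prob", "da_prob", "hr_prob")])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(t1$state[1], "NNN")
  expect_equal(t1$overall_prob[1], 1)
})

test_that("a constant-normal input yields a single-state trace at probability 1", {
  sc <- neutral_rest_scenario(duration_min = 20)
  th <- simulate_thermal(sc)
  hr <- integrate_hr(sc$params, 0, sc$exercise$duration_min,
                     hr_rest = sc$subject$hr_rest)
  tr <- run_health_sequence(th, hr, sc)
  expect_equal(unique(tr$state), "NNN")
  expect_true(all(tr$overall_prob == 1))
})
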