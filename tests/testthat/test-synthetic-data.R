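test_that("trial generation is deterministic and respects the task design", {
  a <- generate_trials(200, seed = 11)
  b <- generate_trials(200, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_trials(200, seed = 12)
  expect_false(identical(a$chosen_offer, c$chosen_offer))

  expect_s3_class(a, "trial_table")
  expect_true(all(a$offer1_mag %in% c(125, 165, 240)))
  expect_true(all(a$offer1_prob[a$offer1_mag == 125] == 1))
  expect_true(all(a$offer1_side != a$offer2_side))
  expect_true(is.na(a$prev_chosen_offer[1]))
  expect_equal(a$prev_chosen_offer[-1], a$chosen_offer[-200])
})

test_that("the default chooser picks the higher-EV offer about 80% of the time", {
  tr <- generate_trials(4000, seed = 21)
  uneq <- tr$ev1 != tr$ev2
  hi <- ifelse(tr$ev1 > tr$ev2, 1L, 2L)
  p <- mean(tr$chosen_offer[uneq] == hi[uneq])
  expect_gt(p, 0.77)
  expect_lt(p, 0.83)
})

test_that("choice-temperature calibration lands near the default beta", {
  b <- calibrate_choice_temperature(target = 0.8, seed = 7)
  expect_gt(b, 0.02)
  expect_lt(b, 0.035)
})

test_that("area specification validates inputs and correlation structure", {
  expect_error(area_spec("x", 5, 10), "order_index")
  expect_error(area_spec("x", 1, 10, ou_tau_mean_ms = -1))
  # alignment and inhibition share the ev2 weight; too-strong settings are
  # jointly infeasible and must be rejected
  bad <- area_spec("x", 1, 10,
                   weight_correlations = c(integration = 0.5,
                                           alignment = 0.9,
                                           inhibition = -0.9))
  expect_error(mpfcgradient:::weight_covariance(bad),
               "non-positive-semidefinite")
})

test_that("drawn neuron populations realize the target weight correlation", {
  a <- area_spec("big", 1, 2000)
  ns <- mpfcgradient:::draw_neuron_specs(a, seed = 31)
  r_int <- cor(ns$beta_prob1, ns$beta_mag1)
  r_inh <- cor(ns$beta_ev1_e2, ns$beta_ev2_e2)
  # Fisher-z SE at 2000 neurons is ~0.022 in z units; 0.07 in r is ~3 SE
  expect_lt(abs(r_int - 0.5), 0.07)
  expect_lt(abs(r_inh + 0.5), 0.07)
  expect_equal(mean(ns$baseline_rate), 5, tolerance = 0.05)
})

test_that("spike simulation is reproducible and baseline-calibrated", {
  tr <- generate_trials(40, seed = 41)
  a <- area_spec("rep", 1, 5)
  s1 <- simulate_area(tr, a, seed = 42)
  s2 <- simulate_area(tr, a, seed = 42)
  expect_identical(s1$spikes$spikes, s2$spikes$spikes)
  s3 <- simulate_area(tr, a, seed = 43)
  expect_false(identical(nrow(s1$spikes$spikes), nrow(s3$spikes$spikes)) &&
               identical(s1$spikes$spikes, s3$spikes$spikes))

  # homogeneous-Poisson preset: mean pre-trial rate matches the 5 sp/s target
  sim <- cached_poisson()
  br <- baseline_rates(sim$spikes, sim$trials, window = c(-2, 0))
  expect_equal(br$mean_rate, 5, tolerance = 0.02)
})

test_that("pre-offer activity is independent of offer value", {
  sim <- cached_sim()  # tuned population
  ep <- epoch("pre", "offer1", -1000, 1000)
  r <- epoch_rates(bin_spikes(sim$spikes, ep, sim$trials))
  tun <- value_tuning(r, sim$trials$ev1)
  expect_lt(mean(tun$selective, na.rm = TRUE), 0.15)
})

test_that("tuning weights drive epoch-1 rates in the right direction", {
  sim <- cached_sim()
  r1 <- epoch_rates(bin_spikes(sim$spikes, default_epochs()$epoch1, sim$trials))
  tun <- value_tuning(r1, sim$trials$ev1)
  # sign of the measured correlation should track the ground-truth weight
  agree <- sign(tun$r) == sign(sim$neurons$beta_ev1_e1)
  expect_gt(mean(agree, na.rm = TRUE), 0.7)
})

test_that("gradient dataset generation orders areas and rejects duplicates", {
  areas <- list(area_spec("a2", 2, 3), area_spec("a1", 1, 3))
  ds <- generate_gradient_dataset(areas, n_trials = 20, seed = 51)
  expect_equal(vapply(ds, `[[`, integer(1), "order_index"), 1:2)
  expect_equal(vapply(ds, `[[`, character(1), "area"), c("a1", "a2"))
  expect_s3_class(ds[[1]]$trials, "trial_table")
  expect_s3_class(ds[[1]]$spikes, "spike_train_set")
  # sessions are independent draws per area
  expect_false(identical(ds[[1]]$trials$ev1, ds[[2]]$trials$ev1))
  dup <- list(area_spec("a", 1, 3), area_spec("b", 1, 3))
  expect_error(generate_gradient_dataset(dup, n_trials = 10), "distinct")
})
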