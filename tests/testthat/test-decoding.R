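test_that("the decoder battery covers the twelve documented labels", {
  specs <- decoder_label_specs()
  expect_equal(nrow(specs), 12)
  expect_false(anyDuplicated(specs$name) > 0)
  expect_true(all(specs$epoch %in% c("epoch1", "epoch2", "choice",
                                     "postchoice")))
})

test_that("binary labels follow the mean-split rule with ties to the low class", {
  tr <- tiny_trials(6)
  lab <- mpfcgradient:::make_decoder_label(tr, "ev1_epoch1")
  expect_equal(lab, tr$ev1 > mean(tr$ev1))
  # exact tie with the mean goes to the low class
  tr2 <- tr; tr2$ev1 <- rep(c(10, 20, 30), 2); tr2$offer1_prob <- 1
  tr2$offer1_mag <- tr2$ev1
  lab2 <- mpfcgradient:::make_decoder_label(tr2, "ev1_epoch1")
  tied <- abs(tr2$ev1 - mean(tr2$ev1)) < 1e-12
  expect_false(any(lab2[tied]))
  # first trial of lagged labels is NA
  labp <- mpfcgradient:::make_decoder_label(tr, "prev_choice_choice")
  expect_true(is.na(labp[1]))
  expect_error(mpfcgradient:::make_decoder_label(tr, "nope"), "unknown")
})

test_that("pseudo-population construction validates labels and draw shapes", {
  rates <- matrix(rnorm(5 * 40), 5, 40)
  labels <- rep(c(TRUE, FALSE), 20)
  pp <- build_pseudopopulation(rates, labels, n_pseudotrials = 30)
  expect_s3_class(pp, "pseudo_population")
  set.seed(1)
  m <- draw_pseudotrials(pp)
  expect_equal(dim(m$low), c(5, 30))
  expect_equal(dim(m$high), c(5, 30))
  # every drawn value must come from the right class pool
  expect_true(all(m$low[1, ] %in% rates[1, !labels]))
  expect_true(all(m$high[1, ] %in% rates[1, labels]))
  expect_error(build_pseudopopulation(rates, rep(TRUE, 40)), "two observed")
  # NA labels are dropped, not counted as a level
  lab_na <- labels; lab_na[1:4] <- NA
  expect_silent(build_pseudopopulation(rates, lab_na, 10))
})

test_that("a separable population decodes perfectly and its shuffle sits at chance", {
  set.seed(2)
  n_tr <- 80
  labels <- rep(c(FALSE, TRUE), n_tr / 2)
  rates <- matrix(rnorm(10 * n_tr), 10, n_tr) +
    matrix(4 * labels, 10, n_tr, byrow = TRUE)
  pp <- build_pseudopopulation(rates, labels, n_pseudotrials = 60)
  res <- decode_label(pp, n_reps = 25, seed = 5, label = "sep")
  expect_s3_class(res, "decoder_result")
  expect_gt(res$mean, 0.95)
  expect_equal(res$shuffle_mean, 0.5, tolerance = 0.1 / 0.5)
  expect_length(res$accuracies, 25)
  expect_false(res$degenerate)
  # deterministic under a fixed seed
  res2 <- decode_label(pp, n_reps = 25, seed = 5, label = "sep")
  expect_identical(res$accuracies, res2$accuracies)
  res3 <- decode_label(pp, n_reps = 25, seed = 6, label = "sep")
  # real accuracies saturate at 1; the shuffle stream reveals the seed change
  expect_false(identical(res$shuffle_accuracies, res3$shuffle_accuracies))
})

test_that("an uninformative population is flagged degenerate or decodes at chance", {
  rates <- matrix(5, 4, 40)
  labels <- rep(c(TRUE, FALSE), 20)
  pp <- build_pseudopopulation(rates, labels, n_pseudotrials = 20)
  res <- decode_label(pp, n_reps = 5, seed = 1, shuffle = FALSE)
  expect_true(res$degenerate)
})

test_that("the battery returns one row per decodable label and respects decimation", {
  sim <- cached_sim()
  ds <- list(area = "fix", order_index = 1L, trials = sim$trials,
             spikes = sim$spikes)
  bat <- decoder_battery(ds, n_pseudotrials = 60, n_reps = 3, seed = 9,
                         shuffle = FALSE)
  expect_equal(sort(bat$table$label), sort(decoder_label_specs()$name))
  expect_true(all(bat$table$n_neurons == 40))
  expect_length(bat$skipped, 0)

  dec <- decoder_battery(ds, n_pseudotrials = 60, n_reps = 3, seed = 9,
                         shuffle = FALSE, decimate_to = 15)
  expect_true(all(dec$table$n_neurons == 15))
  expect_true(all(dec$table$decimated))
  expect_error(decoder_battery(ds, n_pseudotrials = 10, n_reps = 1,
                               decimate_to = 100), "decimate")
})

test_that("multinomial EV control separates a value-coding population", {
  set.seed(4)
  n_tr <- 240
  ev <- c(runif(n_tr - 30, 0, 240), rep(125, 30))  # point mass like the task
  rates <- rbind(outer(rep(1, 6), ev / 30) + matrix(rnorm(6 * n_tr, 0, 0.5),
                                                    6, n_tr))
  res <- multinomial_ev_decoder(rates, ev, n_pseudotrials = 40, n_reps = 5,
                                seed = 3)
  expect_equal(res$n_bins, 6)
  expect_gt(res$overall, 2 / 6)      # well above 6-class chance
  expect_length(res$per_class, 6)
  # width binning is available and also runs
  resw <- multinomial_ev_decoder(rates, ev, binning = "width",
                                 n_pseudotrials = 40, n_reps = 2, seed = 3)
  expect_gt(resw$overall, 1 / 6)
})

test_that("gradient-order test handles scalar and distribution modes", {
  gt <- gradient_order_test(c(63.4, 67.1, 69.8, 71.9), 1:4)
  expect_equal(gt$rho, 1)
  expect_equal(gt$mode, "scalar")
  expect_equal(gt$p, 1 / 12)  # exact one-of-24 orderings x2 tails

  gt2 <- gradient_order_test(c(3.11, 3.69, 0.75, 5.06), 1:4)
  expect_equal(gt2$rho, 0.4)

  dists <- list(rnorm(50, 1), rnorm(50, 2), rnorm(50, 3), rnorm(50, 4))
  gd <- gradient_order_test(dists, 1:4)
  expect_equal(gd$mode, "distribution")
  expect_gt(gd$rho, 0.5)
  expect_error(gradient_order_test(c(1, 1, 1, 1), 1:4), "tied")
})
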