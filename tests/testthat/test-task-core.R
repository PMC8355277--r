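test_that("expected value is magnitude times probability, with domain checks", {
  expect_equal(expected_value(240, 0.5), 120)
  expect_equal(expected_value(125, 1.0), 125)
  expect_equal(expected_value(165, 0.0), 0)
  # bilinearity in magnitude
  m <- runif(20, 0, 300); p <- runif(20)
  expect_equal(expected_value(2 * m, p), 2 * expected_value(m, p))
  expect_error(expected_value(100, 1.2), "probability")
  expect_error(expected_value(100, -0.1), "probability")
  expect_error(expected_value(-5, 0.5), "magnitude")
})

test_that("binning uses half-open 20-ms bins and conserves counts", {
  tr <- tiny_trials(3)
  sp <- data.frame(neuron_id = 1L, trial_id = 1L,
                   spike_time_s = c(0.010, 0.055, 0.490))
  sts <- make_sts(sp, 1, tr$trial_id)
  cnt <- bin_spikes(sts, default_epochs()$epoch1, tr)
  expect_equal(dim(cnt), c(1, 3, 25))
  expect_equal(sum(cnt), 3)
  expect_equal(cnt[1, 1, c(1, 3, 25)], c(1L, 1L, 1L))

  # right-edge spike belongs to the next bin; epoch-end spike is excluded
  sp2 <- data.frame(neuron_id = 1L, trial_id = 1L,
                    spike_time_s = c(0.020, 0.500))
  cnt2 <- bin_spikes(make_sts(sp2, 1, tr$trial_id), default_epochs()$epoch1, tr)
  expect_equal(cnt2[1, 1, 2], 1L)
  expect_equal(cnt2[1, 1, 1], 0L)
  expect_equal(sum(cnt2), 1)

  # empty train -> all-zero bins
  empty <- make_sts(data.frame(neuron_id = integer(), trial_id = integer(),
                               spike_time_s = numeric()), 2, tr$trial_id)
  expect_true(all(bin_spikes(empty, default_epochs()$epoch1, tr) == 0))
})

test_that("count conservation holds for arbitrary generated trains", {
  tr <- tiny_trials(4)
  set.seed(99)
  sp <- data.frame(neuron_id = sample(1:3, 200, TRUE),
                   trial_id = sample(tr$trial_id, 200, TRUE),
                   spike_time_s = runif(200, -2, 3.1))
  sts <- make_sts(sp, 3, tr$trial_id)
  for (ep in default_epochs()[c("pretrial", "epoch1", "epoch2", "choice")]) {
    cnt <- bin_spikes(sts, ep, tr)
    lo <- switch(ep$anchor, offer1 = 0, offer2 = 1.0, choice = 2.1) +
      ep$offset_ms / 1000
    hi <- lo + ep$duration_ms / 1000
    expect_equal(sum(cnt), sum(sp$spike_time_s >= lo & sp$spike_time_s < hi))
  }
})

test_that("epoch outside the recorded span raises a coverage error", {
  tr <- tiny_trials(2)
  sts <- make_sts(data.frame(neuron_id = 1L, trial_id = 1L,
                             spike_time_s = 0.1), 1, tr$trial_id,
                  span = c(-0.5, 2.0))
  expect_error(bin_spikes(sts, default_epochs()$pretrial, tr),
               "outside recorded span")
  expect_error(bin_spikes(sts, default_epochs()$choice, tr),
               "outside recorded span")
})

test_that("epoch rates reduce counts to spikes/s with optional z-scoring", {
  tr <- tiny_trials(3)
  sp <- data.frame(neuron_id = c(1L, 1L, 1L), trial_id = c(1L, 1L, 1L),
                   spike_time_s = c(0.05, 0.15, 0.35))
  cnt <- bin_spikes(make_sts(sp, 2, tr$trial_id), default_epochs()$epoch1, tr)
  r <- epoch_rates(cnt)
  expect_equal(r[1, 1], 6)  # 3 spikes / 0.5 s
  expect_equal(r[1, 2], 0)

  # z-scored rows have mean 0, SD 1; constant rows flagged and set to 0
  m <- cnt
  m[1, , 1] <- c(1L, 2L, 3L)
  z <- epoch_rates(m, zscore = TRUE)
  expect_equal(mean(z[1, ]), 0)
  expect_equal(sd(z[1, ]), 1)
  expect_true(all(z[2, ] == 0))
  expect_equal(attr(z, "zero_variance"), c(`1` = FALSE, `2` = TRUE),
               ignore_attr = TRUE)
})

test_that("trial table validation enforces the documented invariants", {
  tr <- tiny_trials(4)
  expect_s3_class(tr, "trial_table")
  bad <- as.data.frame(tr); bad$ev1[2] <- bad$ev1[2] + 1
  expect_error(trial_table(bad), "inconsistent")
  bad2 <- as.data.frame(tr); bad2$offer1_prob[1] <- 1.5
  expect_error(trial_table(bad2), "\\[0, 1\\]")
  bad3 <- as.data.frame(tr); bad3$offer2_side <- bad3$offer1_side
  expect_error(trial_table(bad3), "complementary")
  bad4 <- as.data.frame(tr); bad4$prev_chosen_offer[3] <- 3 - bad4$prev_chosen_offer[3]
  expect_error(trial_table(bad4), "prev_")
})

test_that("trial and spike CSV round-trips preserve the data", {
  tr <- generate_trials(30, seed = 5)
  sim <- simulate_area(tr, area_spec("io", 1, 4), seed = 6)
  td <- tempfile("io-"); dir.create(td); on.exit(unlink(td, recursive = TRUE))
  tp <- file.path(td, "trials.csv"); sp <- file.path(td, "spikes.csv")
  write_trials(tr, tp)
  tr2 <- read_trials(tp)
  expect_equal(as.data.frame(tr2), as.data.frame(tr), tolerance = 1e-12)
  write_spikes(sim$spikes, sp)
  sts2 <- read_spikes(sp, span = sim$spikes$span)
  expect_equal(sts2$spikes$spike_time_s, sim$spikes$spikes$spike_time_s,
               tolerance = 1e-12)
  expect_equal(sts2$neuron_ids, sim$spikes$neuron_ids)
})

test_that("boxcar smoothing preserves the mean of a constant signal", {
  x <- rep(3, 50)
  expect_equal(boxcar_smooth(x), x)
  y <- boxcar_smooth(rnorm(100))
  expect_length(y, 100)
})
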