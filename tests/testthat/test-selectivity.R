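test_that("value tuning recovers exact linear dependence and flags flat neurons", {
  set.seed(1)
  values <- runif(50, 0, 240)
  rates <- rbind(2 * values + 3,      # perfectly tuned
                 -values + 100,       # perfectly anti-tuned
                 rep(4, 50))          # flat
  tun <- value_tuning(rates, values)
  expect_equal(tun$r[1:2], c(1, -1), tolerance = 1e-12)
  expect_equal(tun$p[1:2], c(0, 0))
  expect_true(all(tun$selective[1:2]))
  expect_true(is.na(tun$r[3]) && !tun$selective[3])
  expect_equal(attr(tun, "zero_variance"), c(FALSE, FALSE, TRUE))
  expect_error(value_tuning(rates[, 1:2, drop = FALSE], values[1:2]),
               ">= 3 trials")
})

test_that("population selectivity matches the exact binomial tail", {
  tun <- data.frame(selective = c(rep(TRUE, 20), rep(FALSE, 80)))
  pop <- population_selectivity(tun, null_rate = 0.05)
  expect_equal(pop$n, 100)
  expect_equal(pop$k, 20)
  expect_equal(pop$proportion, 0.2)
  expect_equal(pop$p_value,
               binom.test(20, 100, 0.05, alternative = "greater")$p.value)
})

test_that("tuned population is selective; untuned one sits at the alpha rate", {
  sim <- cached_sim()
  r1 <- epoch_rates(bin_spikes(sim$spikes, default_epochs()$epoch1, sim$trials))
  pop <- population_selectivity(value_tuning(r1, sim$trials$ev1))
  expect_lt(pop$p_value, 1e-3)
  expect_gt(pop$proportion, 3 * 0.05)  # far above the alpha null rate

  psim <- cached_poisson()
  rp <- epoch_rates(bin_spikes(psim$spikes, default_epochs()$epoch1, psim$trials))
  popp <- population_selectivity(value_tuning(rp, psim$trials$ev1))
  expect_lt(popp$proportion, 0.15)
})

test_that("selectivity timecourse rises after offer onset for tuned neurons", {
  sim <- cached_sim()
  tc <- selectivity_timecourse(sim$spikes, sim$trials, sim$trials$ev1,
                               range_s = c(-0.5, 1.0), window_ms = 500,
                               step_ms = 100)
  expect_true(all(c("center_ms", "prop_selective", "mean_r2") %in% names(tc)))
  pre <- tc$prop_selective[tc$center_ms <= -100]
  post <- tc$prop_selective[tc$center_ms >= 300 & tc$center_ms <= 600]
  expect_gt(mean(post), mean(pre))
  expect_error(selectivity_timecourse(sim$spikes, sim$trials, sim$trials$ev1,
                                      window_ms = 500, step_ms = 30),
               "divide")
})

test_that("latency methods report bin centers with earliest-bin tie-breaks", {
  # deterministic counts: one neuron, identical trials
  tr <- tiny_trials(10)
  nb <- 25; bw <- 20
  counts <- array(0L, dim = c(1, 10, nb))
  counts[1, , 10] <- 5L            # clear peak in bin 10
  counts[1, , 15] <- 5L            # tied peak later -> earliest wins
  counts[1, , ] <- counts[1, , ] + 1L
  attr(counts, "bin_width_ms") <- bw
  attr(counts, "neuron_ids") <- 1L
  ep <- default_epochs()$epoch1
  attr(counts, "epoch") <- ep
  pk <- response_latency(counts, "peak")
  expect_equal(pk$latency_ms, (10 - 0.5) * bw)
  pc <- response_latency(counts, "peak_change")
  expect_equal(pc$latency_ms, (10 - 0.5) * bw)

  sd2 <- response_latency(counts, "first_change_2sd")
  expect_equal(sd2$latency_ms, (10 - 0.5) * bw)

  # value-locked response starting in bin 5: onset_to_sig finds bin 5
  values <- seq_len(10)
  c2 <- array(0L, dim = c(1, 10, nb))
  for (b in 5:nb) c2[1, , b] <- as.integer(values)
  c2[1, , 12] <- c2[1, , 12] + 20L  # peak at bin 12
  attr(c2, "bin_width_ms") <- bw; attr(c2, "neuron_ids") <- 1L
  attr(c2, "epoch") <- ep
  on <- response_latency(c2, "onset_to_sig", values = values)
  expect_equal(on$latency_ms, (5 - 0.5) * bw)
  s2p <- response_latency(c2, "sig_to_peak", values = values)
  expect_equal(s2p$latency_ms, (12 - 5) * bw)
  expect_error(response_latency(c2, "onset_to_sig"), "requires")

  # peak before onset -> negative elapsed time -> NA
  c3 <- c2
  c3[1, , 2] <- c3[1, , 2] + 50L
  neg <- response_latency(c3, "sig_to_peak", values = values)
  expect_true(is.na(neg$latency_ms))
})

test_that("latency ANOVA detects an area effect and rejects degenerate input", {
  set.seed(3)
  d <- expand.grid(area = paste0("a", 1:4), offer = 1:2, rep = 1:30)
  d$latency_ms <- 200 + 30 * as.integer(d$area) + rnorm(nrow(d), 0, 10)
  res <- latency_anova(d)
  expect_lt(res$p_area, 1e-6)
  expect_gt(res$p_offer, 0.001)  # no offer effect built in
  expect_named(res, c("F_area", "p_area", "F_offer", "p_offer", "table"))

  d2 <- d[!(d$area == "a1" & d$offer == 1) | d$rep == 1, ]
  expect_error(latency_anova(d2), "fewer than 2")
  d3 <- d; d3$latency_ms <- 100
  expect_error(latency_anova(d3), "zero variance")
})
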