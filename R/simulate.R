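# Synthetic two-offer risky-choice datasets: task trials with sigmoidal
# choice behaviour, and doubly-stochastic Poisson spike trains whose latent
# rate is baseline + epoch-gated linear value tuning + an Ornstein-Uhlenbeck
# (OU) fluctuation. The OU term has an exactly exponential autocovariance,
# so the intrinsic-timescale estimator faces a well-posed recovery problem.

task_timing <- function() {
  # offer 1 at 0 for 400 ms + 600 ms blank; offer 2 at 1.0 s likewise;
  # 100 ms fixation then choice at 2.1 s; trials carry a 2-s pre-offer span.
  list(t_offer1 = 0, t_offer2 = 1.0, t_choice = 2.1, span = c(-2.0, 3.1))
}

#' Behavioural model of the simulated chooser
#'
#' Choices follow a logistic (softmax) rule on the expected-value difference:
#' `P(choose offer 1) = plogis(beta * (ev1 - ev2) + side_bias * s1)` where
#' `s1` is +1 when offer 1 is on the left. `beta` is in 1/uL.
#'
#' @param beta Choice temperature (inverse), per uL of EV difference;
#'   default reproduces roughly 80% higher-EV choices under the default task
#'   (see [calibrate_choice_temperature()]).
#' @param side_bias Additive logit bias toward the left offer (default 0).
#' @return A `"behavior_spec"` list.
#' @export
behavior_spec <- function(beta = 0.0264, side_bias = 0) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0)
  structure(list(beta = beta, side_bias = side_bias), class = "behavior_spec")
}

#' Calibrate the choice temperature to a target accuracy
#'
#' Finds by root-finding the logistic slope `beta` at which the simulated
#' chooser picks the higher-EV offer on a target fraction of unequal-EV
#' trials, using a Monte-Carlo sample of offer pairs from the task's offer
#' distribution.
#'
#' @param target Target higher-EV choice probability (default 0.8).
#' @param n_trials Monte-Carlo sample size (default 10000).
#' @param seed RNG seed for the offer sample.
#' @return Calibrated `beta` (1/uL).
#' @export
calibrate_choice_temperature <- function(target = 0.8, n_trials = 10000,
                                         seed = 1L) {
  set.seed(substream_seed(seed, "calibrate"))
  o1 <- sample_offers(n_trials)
  o2 <- sample_offers(n_trials)
  d <- abs(o1$mag * o1$prob - o2$mag * o2$prob)
  d <- d[d > 0]
  f <- function(b) mean(stats::plogis(b * d)) - target
  stats::uniroot(f, c(1e-6, 5), tol = 1e-8)$root
}

# One draw per trial from the task's offer distribution: 43.75% medium
# (165 uL) gamble, 43.75% large (240 uL) gamble, 12.5% safe (125 uL, p = 1);
# gamble probabilities uniform on [0, 1].
sample_offers <- function(n) {
  type <- sample(c("medium", "large", "safe"), n, replace = TRUE,
                 prob = c(0.4375, 0.4375, 0.125))
  mag <- c(medium = 165, large = 240, safe = 125)[type]
  prob <- ifelse(type == "safe", 1, stats::runif(n))
  list(mag = unname(mag), prob = prob, type = type)
}

#' Generate a synthetic trial table
#'
#' Samples offers from the task's offer distribution, draws sides at random,
#' simulates choices from the logistic rule in [behavior_spec()], resolves
#' rewards by the chosen offer's probability, and fills previous-trial lag
#' fields. Deterministic under a fixed seed.
#'
#' @param n_trials Number of trials (>= 1).
#' @param behavior A [behavior_spec()].
#' @param seed Master seed.
#' @return A validated [trial_table()].
#' @export
generate_trials <- function(n_trials, behavior = behavior_spec(), seed = 1L) {
  stopifnot(n_trials >= 1, inherits(behavior, "behavior_spec"))
  set.seed(substream_seed(seed, "trials"))
  tm <- task_timing()
  o1 <- sample_offers(n_trials)
  o2 <- sample_offers(n_trials)
  side1 <- sample(c("left", "right"), n_trials, replace = TRUE)
  side2 <- ifelse(side1 == "left", "right", "left")
  ev1 <- expected_value(o1$mag, o1$prob)
  ev2 <- expected_value(o2$mag, o2$prob)
  s1 <- ifelse(side1 == "left", 1, -1)
  p_choose1 <- stats::plogis(behavior$beta * (ev1 - ev2) +
                             behavior$side_bias * s1)
  chosen <- ifelse(stats::runif(n_trials) < p_choose1, 1L, 2L)
  chosen_side <- ifelse(chosen == 1L, side1, side2)
  chosen_prob <- ifelse(chosen == 1L, o1$prob, o2$prob)
  rewarded <- stats::runif(n_trials) < chosen_prob
  trial_table(data.frame(
    trial_id = seq_len(n_trials),
    offer1_mag = o1$mag, offer1_prob = o1$prob, offer1_side = side1,
    offer2_mag = o2$mag, offer2_prob = o2$prob, offer2_side = side2,
    ev1 = ev1, ev2 = ev2,
    chosen_offer = chosen, chosen_side = chosen_side, rewarded = rewarded,
    prev_chosen_offer = c(NA_integer_, chosen[-n_trials]),
    prev_rewarded = c(NA, rewarded[-n_trials]),
    t_offer1 = tm$t_offer1, t_offer2 = tm$t_offer2, t_choice = tm$t_choice,
    stringsAsFactors = FALSE
  ))
}

weight_names <- c("beta_prob1", "beta_mag1", "beta_ev1_e1", "beta_ev1_e2",
                  "beta_ev2_e2", "beta_side", "beta_choice",
                  "beta_chosen_value", "beta_unchosen_value",
                  "beta_prev_choice", "beta_prev_reward")

#' Specify one synthetic area
#'
#' An area is a population of OU-rate Poisson neurons with linear value
#' tuning. `snr_scale` multiplies every tuning-weight SD, so the gradient
#' preset realizes increasing tuning signal-to-noise with `order_index`.
#' `weight_correlations` are the target population correlations among
#' tuning weights: positive probability-magnitude coupling (feature
#' integration), positive offer-1/offer-2 value coupling across epochs
#' (attentional alignment), and negative offer-1/offer-2 value coupling
#' within epoch 2 (mutual inhibition).
#'
#' @param name Area label.
#' @param order_index Gradient rank 1-4.
#' @param n_neurons Population size.
#' @param snr_scale Multiplier on the tuning-weight SD (default 1).
#' @param ou_tau_mean_ms OU timescale, ms (all neurons share it).
#' @param weight_correlations Named vector `integration`, `alignment`,
#'   `inhibition` (defaults 0.5, 0.5, -0.5).
#' @param baseline_mean Mean baseline rate, spikes/s (default 5).
#' @param baseline_cv Lognormal CV of baselines across neurons (default 0.3).
#' @param weight_sd Tuning-weight SD at `snr_scale = 1`, spikes/s per z-unit
#'   of regressor (default 0.14).
#' @param ou_sigma_frac OU stationary SD as a fraction of each neuron's
#'   baseline (default 0.4, i.e. baseline = 2.5 sigma, keeping rate clipping
#'   at zero below about 1% of time; 0 gives homogeneous-Poisson neurons).
#' @param noise_sd Per-trial white rate jitter SD, spikes/s (default 0).
#' @return An `"area_spec"` list.
#' @export
area_spec <- function(name, order_index, n_neurons, snr_scale = 1,
                      ou_tau_mean_ms = 200,
                      weight_correlations = c(integration = 0.5,
                                              alignment = 0.5,
                                              inhibition = -0.5),
                      baseline_mean = 5, baseline_cv = 0.3,
                      weight_sd = 0.14, ou_sigma_frac = 0.4, noise_sd = 0) {
  stopifnot(order_index %in% 1:4, n_neurons >= 1, snr_scale >= 0,
            ou_tau_mean_ms > 0, baseline_mean > 0, ou_sigma_frac >= 0)
  wc <- weight_correlations
  stopifnot(all(c("integration", "alignment", "inhibition") %in% names(wc)))
  structure(list(name = name, order_index = as.integer(order_index),
                 n_neurons = as.integer(n_neurons), snr_scale = snr_scale,
                 ou_tau_mean_ms = ou_tau_mean_ms, weight_correlations = wc,
                 baseline_mean = baseline_mean, baseline_cv = baseline_cv,
                 weight_sd = weight_sd, ou_sigma_frac = ou_sigma_frac,
                 noise_sd = noise_sd),
            class = "area_spec")
}

# Population covariance of the tuning weights implementing the target
# correlations; errors if the implied correlation matrix is not PSD.
weight_covariance <- function(area) {
  k <- length(weight_names)
  C <- diag(k)
  dimnames(C) <- list(weight_names, weight_names)
  set_cor <- function(C, a, b, v) { C[a, b] <- v; C[b, a] <- v; C }
  wc <- area$weight_correlations
  C <- set_cor(C, "beta_prob1", "beta_mag1", wc[["integration"]])
  C <- set_cor(C, "beta_ev1_e1", "beta_ev2_e2", wc[["alignment"]])
  C <- set_cor(C, "beta_ev1_e2", "beta_ev2_e2", wc[["inhibition"]])
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("weight_correlations imply a non-positive-semidefinite ",
         "correlation matrix (min eigenvalue ", signif(min(ev), 3), ")")
  sdv <- rep(area$weight_sd * area$snr_scale, k)
  diag(sdv, k) %*% C %*% diag(sdv, k)
}

draw_neuron_specs <- function(area, seed) {
  set.seed(substream_seed(seed, paste0("weights-", area$name)))
  n <- area$n_neurons
  Sigma <- weight_covariance(area)
  W <- if (all(Sigma == 0)) matrix(0, n, length(weight_names)) else
    MASS::mvrnorm(n, mu = rep(0, length(weight_names)), Sigma = Sigma)
  colnames(W) <- weight_names
  sdlog <- sqrt(log(1 + area$baseline_cv^2))
  baseline <- stats::rlnorm(n, meanlog = log(area$baseline_mean) - sdlog^2 / 2,
                            sdlog = sdlog)
  data.frame(neuron_id = seq_len(n), baseline_rate = baseline,
             as.data.frame(W),
             ou_tau = area$ou_tau_mean_ms,
             ou_sigma = area$ou_sigma_frac * baseline,
             noise_sd = area$noise_sd)
}

# Per-trial regressors on the generator's own z/±1 scale.
trial_regressors <- function(trials) {
  chosen_ev <- ifelse(trials$chosen_offer == 1L, trials$ev1, trials$ev2)
  unchosen_ev <- ifelse(trials$chosen_offer == 1L, trials$ev2, trials$ev1)
  pm1 <- function(x) ifelse(is.na(x), 0, ifelse(x, 1, -1))
  list(
    zp1 = zscore(trials$offer1_prob), zm1 = zscore(trials$offer1_mag),
    zev1 = zscore(trials$ev1), zev2 = zscore(trials$ev2),
    zcv = zscore(chosen_ev), zuv = zscore(unchosen_ev),
    s1 = ifelse(trials$offer1_side == "left", 1, -1),
    cs = ifelse(trials$chosen_side == "left", 1, -1),
    ch = ifelse(trials$chosen_offer == 1L, 1, -1),
    pc = pm1(trials$prev_chosen_offer == 1L),
    pr = pm1(trials$prev_rewarded)
  )
}

#' Simulate one area's spike trains
#'
#' Each neuron's latent rate is `baseline + (epoch-gated tuning) + OU(t)`,
#' clipped at zero, and spikes are drawn as an inhomogeneous Poisson process
#' on a `dt_ms` grid. Tuning terms are gated by trial period: offer-1 tuning
#' (probability, magnitude, offer-1 value, offer side) between offer-1 and
#' offer-2 onset; offer-value memory and offer-2 value between offer-2 onset
#' and choice; choice, chosen side, chosen/unchosen value and previous-trial
#' terms from choice fixation to the end of the trial. The 2-s pre-offer
#' span carries baseline + OU only, so it stays independent of task
#' variables as the timescale analysis requires.
#'
#' @param trials A [trial_table()].
#' @param area An [area_spec()].
#' @param seed Master seed (weight and spike draws use independent
#'   substreams derived from it and the area name).
#' @param dt_ms Simulation time step, ms (default 10).
#' @return List with `spikes` (a [spike_train_set()]) and `neurons`
#'   (the ground-truth neuron table: baseline, tuning weights, OU
#'   parameters).
#' @export
simulate_area <- function(trials, area, seed = 1L, dt_ms = 10) {
  stopifnot(inherits(area, "area_spec"), nrow(trials) >= 1)
  tm <- task_timing()
  neurons <- draw_neuron_specs(area, seed)
  reg <- trial_regressors(trials)
  nt <- nrow(trials)
  dt_s <- dt_ms / 1000
  tgrid <- seq(tm$span[1], tm$span[2] - dt_s / 2, by = dt_s)
  nb <- length(tgrid)
  seg1 <- tgrid >= tm$t_offer1 & tgrid < tm$t_offer2
  seg2 <- tgrid >= tm$t_offer2 & tgrid < tm$t_choice
  seg3 <- tgrid >= tm$t_choice
  set.seed(substream_seed(seed, paste0("spikes-", area$name)))
  acc_n <- vector("list", area$n_neurons)
  acc_t <- vector("list", area$n_neurons)
  acc_s <- vector("list", area$n_neurons)
  for (i in seq_len(area$n_neurons)) {
    ns <- neurons[i, ]
    sig1 <- ns$beta_prob1 * reg$zp1 + ns$beta_mag1 * reg$zm1 +
      ns$beta_ev1_e1 * reg$zev1 + ns$beta_side * reg$s1
    sig2 <- ns$beta_ev1_e2 * reg$zev1 + ns$beta_ev2_e2 * reg$zev2
    sig3 <- ns$beta_choice * reg$ch + ns$beta_side * reg$cs +
      ns$beta_chosen_value * reg$zcv + ns$beta_unchosen_value * reg$zuv +
      ns$beta_prev_choice * reg$pc + ns$beta_prev_reward * reg$pr
    rate <- matrix(ns$baseline_rate, nt, nb)
    if (ns$noise_sd > 0) rate <- rate + stats::rnorm(nt, 0, ns$noise_sd)
    rate[, seg1] <- rate[, seg1] + sig1
    rate[, seg2] <- rate[, seg2] + sig2
    rate[, seg3] <- rate[, seg3] + sig3
    if (ns$ou_sigma > 0) {
      a <- exp(-dt_ms / ns$ou_tau)
      innov_sd <- ns$ou_sigma * sqrt(1 - a^2)
      x <- stats::rnorm(nt, 0, ns$ou_sigma)
      rate[, 1] <- rate[, 1] + x
      for (b in 2:nb) {
        x <- a * x + stats::rnorm(nt, 0, innov_sd)
        rate[, b] <- rate[, b] + x
      }
    }
    rate[rate < 0] <- 0
    counts <- matrix(stats::rpois(nt * nb, rate * dt_s), nt, nb)
    nz <- which(counts > 0)
    if (length(nz)) {
      k <- counts[nz]
      row <- (nz - 1L) %% nt + 1L
      col <- (nz - 1L) %/% nt + 1L
      t0 <- rep(tgrid[col], k)
      acc_t[[i]] <- rep(trials$trial_id[row], k)
      acc_s[[i]] <- t0 + stats::runif(length(t0)) * dt_s
      acc_n[[i]] <- rep(i, length(t0))
    }
  }
  spikes <- data.frame(neuron_id = unlist(acc_n),
                       trial_id = unlist(acc_t),
                       spike_time_s = unlist(acc_s))
  if (!nrow(spikes))
    spikes <- data.frame(neuron_id = integer(), trial_id = integer(),
                         spike_time_s = numeric())
  sts <- spike_train_set(spikes, neuron_ids = seq_len(area$n_neurons),
                         trial_ids = trials$trial_id, span = tm$span)
  list(spikes = sts, neurons = neurons)
}

#' The default four-area gradient preset
#'
#' Population sizes follow the recorded counts (156, 146, 213, 129); tuning
#' SNR and OU timescale both increase strictly with gradient order. The SNR
#' ladder is steep enough that decoding accuracy increases with order despite
#' the third area's larger population.
#'
#' @return List of four [area_spec()]s ordered 1-4.
#' @export
default_gradient_spec <- function() {
  list(
    area_spec("vmPFC", 1, 156, snr_scale = 0.6, ou_tau_mean_ms = 110),
    area_spec("sgACC", 2, 146, snr_scale = 0.9, ou_tau_mean_ms = 150),
    area_spec("pgACC", 3, 213, snr_scale = 1.0, ou_tau_mean_ms = 320),
    area_spec("dACC", 4, 129, snr_scale = 1.6, ou_tau_mean_ms = 450)
  )
}

#' Generate a full four-area gradient dataset
#'
#' Draws an independent session of trials per area and simulates its spike
#' trains, tagging each dataset with the area's gradient-order index.
#'
#' @param areas List of [area_spec()]s with distinct `order_index`
#'   (default [default_gradient_spec()]).
#' @param n_trials Trials per area (default 500).
#' @param behavior A [behavior_spec()].
#' @param seed Master seed.
#' @param dt_ms Simulation step, ms.
#' @return List of area datasets, each
#'   `list(area, order_index, trials, spikes, neurons)`, sorted by order.
#' @export
generate_gradient_dataset <- function(areas = default_gradient_spec(),
                                      n_trials = 500,
                                      behavior = behavior_spec(),
                                      seed = 1L, dt_ms = 10) {
  ord <- vapply(areas, function(a) a$order_index, integer(1))
  if (anyDuplicated(ord)) stop("area order_index values must be distinct")
  out <- lapply(areas, function(a) {
    trials <- generate_trials(n_trials, behavior,
                              seed = substream_seed(seed, paste0("session-", a$name)))
    sim <- simulate_area(trials, a, seed = seed, dt_ms = dt_ms)
    list(area = a$name, order_index = a$order_index, trials = trials,
         spikes = sim$spikes, neurons = sim$neurons)
  })
  out[order(ord)]
}
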