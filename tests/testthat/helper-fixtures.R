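# Shared fixtures, built in code. Heavier simulations are cached per session
# so several test files can reuse one dataset.

# Minimal hand-built trial table (n trials, deterministic).
tiny_trials <- function(n = 6) {
  mag1 <- rep(c(165, 240, 125), length.out = n)
  prob1 <- rep(c(0.5, 0.25, 1), length.out = n)
  mag2 <- rep(c(240, 125, 165), length.out = n)
  prob2 <- rep(c(0.4, 1, 0.8), length.out = n)
  side1 <- rep(c("left", "right"), length.out = n)
  chosen <- rep(c(1L, 2L), length.out = n)
  rewarded <- rep(c(TRUE, FALSE), length.out = n)
  trial_table(data.frame(
    trial_id = seq_len(n),
    offer1_mag = mag1, offer1_prob = prob1, offer1_side = side1,
    offer2_mag = mag2, offer2_prob = prob2,
    offer2_side = ifelse(side1 == "left", "right", "left"),
    ev1 = mag1 * prob1, ev2 = mag2 * prob2,
    chosen_offer = chosen,
    chosen_side = ifelse(chosen == 1L, side1,
                         ifelse(side1 == "left", "right", "left")),
    rewarded = rewarded,
    prev_chosen_offer = c(NA_integer_, chosen[-n]),
    prev_rewarded = c(NA, rewarded[-n]),
    t_offer1 = 0, t_offer2 = 1.0, t_choice = 2.1,
    stringsAsFactors = FALSE
  ))
}

# Reference z-score used when tests build analytic rate matrices.
zscore_test <- function(x) as.numeric(scale(x))

# Spike set from an explicit list: list of data.frames or a single df.
make_sts <- function(df, n_neurons, trial_ids, span = c(-2, 3.1)) {
  spike_train_set(df, neuron_ids = seq_len(n_neurons),
                  trial_ids = trial_ids, span = span)
}

# Session-cached small simulated area with tuning (40 neurons x 250 trials).
cached_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      trials <- generate_trials(250, seed = 301)
      a <- area_spec("fixture", 1, 40, snr_scale = 2, ou_tau_mean_ms = 200)
      sim <- simulate_area(trials, a, seed = 302)
      cache <<- list(trials = trials, spikes = sim$spikes,
                     neurons = sim$neurons)
    }
    cache
  }
})

# Session-cached homogeneous-Poisson area (no tuning, no OU).
cached_poisson <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      trials <- generate_trials(300, seed = 401)
      a <- area_spec("poisson", 1, 60, snr_scale = 0, ou_sigma_frac = 0,
                     baseline_cv = 0)
      sim <- simulate_area(trials, a, seed = 402)
      cache <<- list(trials = trials, spikes = sim$spikes,
                     neurons = sim$neurons)
    }
    cache
  }
})
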