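# Intrinsic-property controls and the behavioural summary: baseline firing
# rates, Fano factors in 100-ms bins, PCA dimensionality of trial-averaged
# time courses, and the higher-EV choice analysis.

#' Baseline firing rates
#'
#' Mean pre-trial firing rate per neuron (across trials), averaged over the
#' population. The default window is the first second of the 2-s pre-offer
#' span, so it does not overlap the final second used informally elsewhere;
#' the window is configurable.
#'
#' @param sts A [spike_train_set()].
#' @param trials A [trial_table()].
#' @param window Window in s relative to offer 1 (default `c(-2, -1)`).
#' @return List `(mean_rate, per_neuron)` in spikes/s.
#' @export
baseline_rates <- function(sts, trials, window = c(-2, -1)) {
  dur <- round((window[2] - window[1]) * 1000)
  ep <- epoch("baseline", "offer1", offset_ms = round(window[1] * 1000),
              duration_ms = dur, bin_width_ms = dur)
  counts <- bin_spikes(sts, ep, trials)
  rates <- epoch_rates(counts)
  per_neuron <- rowMeans(rates)
  list(mean_rate = mean(per_neuron), per_neuron = per_neuron)
}

#' Fano factor within an epoch
#'
#' Segments a 500-ms epoch into 100-ms bins; per neuron and bin, the Fano
#' factor is the across-trial variance of the spike count divided by its
#' mean (1 for a Poisson process). Zero-mean bins are skipped; neurons with
#' all bins zero-mean are excluded with a report. Per-bin FFs are averaged
#' across neurons; the summary `mean_ff` averages those bin means, with an
#' SEM across bins.
#'
#' @param sts A [spike_train_set()].
#' @param trials A [trial_table()].
#' @param ep An [epoch()] whose duration is divisible by `bin_ms`.
#' @param bin_ms Bin width, ms (default 100).
#' @return List `(mean_ff, sem, per_bin, n_neurons, n_excluded)`.
#' @export
fano_factor <- function(sts, trials, ep, bin_ms = 100) {
  if (ep$duration_ms %% bin_ms != 0)
    stop("epoch duration must be divisible by the Fano bin width")
  ep2 <- epoch(ep$name, ep$anchor, ep$offset_ms, ep$duration_ms,
               bin_width_ms = bin_ms)
  counts <- bin_spikes(sts, ep2, trials)
  if (dim(counts)[2] < 2) stop("need >= 2 trials")
  nb <- dim(counts)[3]
  m <- apply(counts, c(1, 3), mean)       # neurons x bins
  v <- apply(counts, c(1, 3), stats::var)
  ff <- v / m
  ff[m == 0] <- NA_real_
  excluded <- rowSums(is.finite(ff)) == 0
  ff_use <- ff[!excluded, , drop = FALSE]
  per_bin <- colMeans(ff_use, na.rm = TRUE)
  list(mean_ff = mean(per_bin), sem = stats::sd(per_bin) / sqrt(nb),
       per_bin = per_bin, n_neurons = sum(!excluded),
       n_excluded = sum(excluded))
}

#' PCA dimensionality of trial-averaged time courses
#'
#' Builds the time x neurons matrix of trial-averaged 20-ms-bin rates within
#' one epoch, z-scores each neuron's time course, eigendecomposes its
#' covariance across time, and reports the explained-variance fractions of
#' the first three principal components plus the successive slopes
#' (differences) PC1 to PC2 and PC2 to PC3.
#'
#' @param sts A [spike_train_set()].
#' @param trials A [trial_table()].
#' @param ep An [epoch()] (20-ms bins).
#' @return List `(fractions, slope_12, slope_23, all_fractions)`.
#' @export
pca_dimensionality <- function(sts, trials, ep) {
  counts <- bin_spikes(sts, ep, trials)
  if (dim(counts)[1] < 3) stop("need >= 3 neurons")
  psth <- t(apply(counts, c(1, 3), mean))  # time x neurons
  psth <- apply(psth, 2, zscore)
  pc <- stats::prcomp(psth, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  f3 <- c(frac, rep(NA_real_, 3))[1:3]
  list(fractions = f3,
       slope_12 = f3[2] - f3[1],
       slope_23 = f3[3] - f3[2],
       all_fractions = frac)
}

#' Behavioural summary: higher-EV choice proportions and the choice curve
#'
#' Computes, per session, the proportion of unequal-EV trials on which the
#' higher-EV offer was chosen; tests the vector of proportions with a
#' one-sample t-test (null 0 as conventionally printed for this task;
#' configurable); and fits a logistic curve of P(choose offer 1) on the EV
#' difference.
#'
#' @param sessions A list of [trial_table()]s (or a single table).
#' @param null Null value for the t-test (default 0).
#' @return List `(proportions, t_test, logistic, skipped_sessions)` where
#'   `logistic` carries the fitted slope (1/uL) and bias (logit units).
#' @export
behavior_summary <- function(sessions, null = 0) {
  if (inherits(sessions, "trial_table")) sessions <- list(sessions)
  props <- numeric(0); skipped <- integer(0)
  all_trials <- list()
  for (s in seq_along(sessions)) {
    tt <- sessions[[s]]
    uneq <- tt$ev1 != tt$ev2
    if (!any(uneq)) { skipped <- c(skipped, s); next }
    hi <- ifelse(tt$ev1 > tt$ev2, 1L, 2L)
    props <- c(props, mean(tt$chosen_offer[uneq] == hi[uneq]))
    all_trials[[length(all_trials) + 1L]] <- tt
  }
  tt_res <- if (length(props) >= 2)
    stats::t.test(props, mu = null) else NULL
  big <- do.call(rbind, lapply(all_trials, as.data.frame))
  fit <- stats::glm(I(chosen_offer == 1L) ~ I(ev1 - ev2),
                    family = stats::binomial(), data = big)
  cf <- stats::coef(fit)
  list(proportions = props,
       t_test = if (!is.null(tt_res))
         list(t = unname(tt_res$statistic), p = tt_res$p.value,
              df = unname(tt_res$parameter), mean = mean(props)) else NULL,
       logistic = list(bias = unname(cf[1]), slope = unname(cf[2])),
       skipped_sessions = skipped)
}
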