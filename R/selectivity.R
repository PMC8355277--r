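# Per-neuron value coding: Pearson correlation of epoch firing rates with
# offer values, a population-level binomial test, a sliding-window
# selectivity timecourse, and five offer-response latency definitions with
# area x offer ANOVAs.

#' Per-neuron value tuning
#'
#' Correlates each neuron's epoch firing rates with a per-trial value
#' regressor (Pearson, two-sided). `r^2` is retained for timecourse
#' averaging. Neurons with zero rate variance get a missing result and a
#' flag rather than an error.
#'
#' @param rates `neurons x trials` rate matrix (from [epoch_rates()]).
#' @param values Per-trial regressor (e.g. offer EV), same trial order.
#' @param alpha Per-neuron significance criterion (default 0.05).
#' @return data.frame `(neuron_id, r, r2, p, selective)`; attribute
#'   `zero_variance` flags neurons without a valid test.
#' @export
value_tuning <- function(rates, values, alpha = 0.05) {
  stopifnot(is.matrix(rates), ncol(rates) == length(values))
  if (ncol(rates) < 3) stop("need >= 3 trials for a correlation test")
  ct <- row_cor_test(rates, values)
  ids <- rownames(rates)
  out <- data.frame(
    neuron_id = if (is.null(ids)) seq_len(nrow(rates)) else as.integer(ids),
    r = ct$r, r2 = ct$r^2, p = ct$p,
    selective = !is.na(ct$p) & ct$p < alpha
  )
  attr(out, "zero_variance") <- is.na(ct$r)
  attr(out, "alpha") <- alpha
  out
}

#' Population selectivity test
#'
#' Asks whether the fraction of individually selective neurons exceeds the
#' per-neuron false-positive rate, with a one-sided exact binomial tail
#' `P(X >= k | n, null_rate)`.
#'
#' @param tuning Result of [value_tuning()] (or any data.frame with a
#'   logical `selective` column).
#' @param null_rate Null selective rate (default 0.05, the per-neuron alpha).
#' @return List `(n, k, proportion, p_value)`.
#' @export
population_selectivity <- function(tuning, null_rate = 0.05) {
  sel <- tuning$selective
  sel <- sel[!is.na(sel)]
  n <- length(sel)
  if (n < 1) stop("no neurons with a valid tuning result")
  k <- sum(sel)
  p <- stats::binom.test(k, n, p = null_rate, alternative = "greater")$p.value
  list(n = n, k = k, proportion = k / n, p_value = p)
}

#' Time-resolved selectivity
#'
#' Slides a window across the trial and reports, per window, the fraction of
#' neurons whose rates correlate with the value regressor and the mean
#' explained variance (r^2) across neurons. Windows are anchored to offer-1
#' onset and reported at their centers.
#'
#' @param sts A [spike_train_set()].
#' @param trials A [trial_table()].
#' @param values Per-trial regressor aligned with `trials`.
#' @param range_s Span covered, s relative to offer 1 (default `c(-0.5, 2.5)`).
#' @param window_ms Window width, ms (default 500).
#' @param step_ms Step between window starts, ms (default 20); must divide
#'   `window_ms`.
#' @param alpha Per-neuron criterion.
#' @return data.frame `(center_ms, prop_selective, mean_r2, n_neurons)`.
#' @export
selectivity_timecourse <- function(sts, trials, values,
                                   range_s = c(-0.5, 2.5),
                                   window_ms = 500, step_ms = 20,
                                   alpha = 0.05) {
  if (window_ms %% step_ms != 0)
    stop("`step_ms` must divide `window_ms`")
  span_ms <- round(diff(range_s) * 1000)
  nb <- span_ms %/% step_ms
  ep <- epoch("timecourse", "offer1", offset_ms = round(range_s[1] * 1000),
              duration_ms = nb * step_ms, bin_width_ms = step_ms)
  counts <- bin_spikes(sts, ep, trials)
  wb <- window_ms %/% step_ms
  n_win <- nb - wb + 1L
  if (n_win < 1) stop("range shorter than one window")
  # cumulative counts along bins -> O(1) window sums
  cum <- aperm(apply(counts, c(1, 2), cumsum), c(2, 3, 1))
  win_sum <- function(i) {
    hi <- cum[, , i + wb - 1L]
    if (i == 1L) hi else hi - cum[, , i - 1L]
  }
  centers <- ep$offset_ms + (seq_len(n_win) - 1L) * step_ms + window_ms / 2
  res <- vapply(seq_len(n_win), function(i) {
    tun <- value_tuning(win_sum(i) / (window_ms / 1000), values, alpha)
    c(mean(tun$selective, na.rm = TRUE), mean(tun$r2, na.rm = TRUE),
      sum(!is.na(tun$r)))
  }, numeric(3))
  data.frame(center_ms = centers, prop_selective = res[1, ],
             mean_r2 = res[2, ], n_neurons = as.integer(res[3, ]))
}

latency_methods <- c("peak", "onset_to_sig", "sig_to_peak", "peak_change",
                     "first_change_2sd")

#' Offer-response latency
#'
#' Per-neuron response latency within a 500-ms offer epoch under five
#' definitions: time of the peak trial-averaged rate (`peak`); first bin
#' whose rates correlate significantly with the value regressor
#' (`onset_to_sig`); time elapsed from that first significant bin to the
#' peak (`sig_to_peak`); time of the largest absolute deviation of the
#' binned rate from its epoch mean (`peak_change`); and the first bin more
#' than 2 SD above or below the epoch mean (`first_change_2sd`, two-sided to
#' admit suppressed responses). Latencies are reported at bin centers; ties
#' break to the earliest bin; neurons with no qualifying bin get `NA` and
#' are excluded from means.
#'
#' @param counts Count tensor from [bin_spikes()] for one offer epoch.
#' @param method One of `r toString(latency_methods)`.
#' @param values Per-trial value regressor (required by the significance-
#'   based methods).
#' @param alpha Per-bin significance criterion (default 0.05).
#' @return data.frame `(neuron_id, latency_ms)`.
#' @export
response_latency <- function(counts, method = latency_methods, values = NULL,
                             alpha = 0.05) {
  method <- match.arg(method)
  bw <- attr(counts, "bin_width_ms")
  nn <- dim(counts)[1]; nb <- dim(counts)[3]
  psth <- colMeans(aperm(counts, c(2, 1, 3)))  # neurons x bins mean rate
  center <- function(b) (b - 0.5) * bw
  need_values <- method %in% c("onset_to_sig", "sig_to_peak")
  if (need_values && is.null(values))
    stop("method '", method, "' requires `values`")
  onset_bin <- NULL
  if (need_values) {
    onset_bin <- rep(NA_integer_, nn)
    for (b in seq_len(nb)) {
      ct <- row_cor_test(matrix(counts[, , b], nn), values)
      hit <- is.na(onset_bin) & !is.na(ct$p) & ct$p < alpha
      onset_bin[hit] <- b
    }
  }
  lat <- switch(method,
    peak = center(apply(psth, 1, which.max)),
    onset_to_sig = ifelse(is.na(onset_bin), NA_real_, center(onset_bin)),
    sig_to_peak = {
      pk <- apply(psth, 1, which.max)
      el <- center(pk) - center(onset_bin)
      ifelse(is.na(onset_bin) | el < 0, NA_real_, el)
    },
    peak_change = {
      dev <- abs(psth - rowMeans(psth))
      center(apply(dev, 1, which.max))
    },
    first_change_2sd = {
      m <- rowMeans(psth)
      s <- apply(psth, 1, stats::sd)
      vapply(seq_len(nn), function(i) {
        b <- which(abs(psth[i, ] - m[i]) > 2 * s[i])
        if (length(b)) center(b[1]) else NA_real_
      }, numeric(1))
    })
  ids <- attr(counts, "neuron_ids")
  data.frame(neuron_id = if (is.null(ids)) seq_len(nn) else ids,
             latency_ms = lat)
}

#' Area-by-offer latency ANOVA
#'
#' Two-way ANOVA (4 areas x 2 offers) on neuron-level latencies, reporting
#' the main effects; missing latencies are dropped listwise.
#'
#' @param latencies data.frame with columns `latency_ms`, `area`, `offer`.
#' @return List `(F_area, p_area, F_offer, p_offer, table)` where `table`
#'   is the full ANOVA table.
#' @export
latency_anova <- function(latencies) {
  stopifnot(all(c("latency_ms", "area", "offer") %in% names(latencies)))
  d <- latencies[!is.na(latencies$latency_ms), , drop = FALSE]
  d$area <- factor(d$area); d$offer <- factor(d$offer)
  cells <- table(d$area, d$offer)
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)
    stop("fewer than 2 observations in cell(s): ",
         paste(rownames(cells)[bad[, 1]], colnames(cells)[bad[, 2]],
               sep = ":", collapse = ", "))
  }
  if (stats::var(d$latency_ms) == 0)
    stop("degenerate input: latencies have zero variance")
  fit <- stats::aov(latency_ms ~ area + offer, data = d)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  if (tab["Residuals", "Sum Sq"] <= 0)
    stop("degenerate input: zero residual variance")
  list(F_area = tab["area", "F value"], p_area = tab["area", "Pr(>F)"],
       F_offer = tab["offer", "F value"], p_offer = tab["offer", "Pr(>F)"],
       table = tab)
}
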