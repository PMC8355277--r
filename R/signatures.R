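# Population signatures of the choice computation: per-neuron OLS weights of
# z-scored epoch rates on task variables, correlated across the population.
# Feature integration = positive probability/magnitude weight correlation in
# epoch 1; attentional alignment = positive correlation between the offer-1
# value weight in epoch 1 and the offer-2 value weight in epoch 2; mutual
# inhibition = negative correlation between the two offer-value weights
# within epoch 2. Unsigned (absolute-weight) correlations measure overlap of
# the contributing populations.

#' Per-neuron value regressions
#'
#' Ordinary least squares of each neuron's (z-scored) epoch rates on one or
#' more per-trial regressors. Regressors are standardized before fitting so
#' weights are comparable across neurons and regressors.
#'
#' @param rates `neurons x trials` matrix, typically z-scored
#'   (`epoch_rates(..., zscore = TRUE)`).
#' @param regressors data.frame or matrix of per-trial regressors (columns
#'   named).
#' @param standardize z-score regressors before fitting (default `TRUE`).
#' @param max_condition Condition-number threshold above which the design is
#'   declared collinear (default 1e6).
#' @return `neurons x regressors` coefficient matrix with attribute
#'   `n_trials`.
#' @export
fit_value_regressions <- function(rates, regressors, standardize = TRUE,
                                  max_condition = 1e6) {
  X <- as.matrix(regressors)
  stopifnot(is.matrix(rates), nrow(X) == ncol(rates))
  if (standardize) X <- apply(X, 2, zscore)
  Xd <- cbind(`(Intercept)` = 1, X)
  kap <- kappa(Xd, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    cm <- abs(stats::cor(X))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    stop("collinear regressors (condition number ", signif(kap, 3),
         "); most correlated pair: ",
         colnames(X)[worst[1]], " and ", colnames(X)[worst[2]])
  }
  # all neurons share the design: solve once
  B <- t(qr.coef(qr(Xd), t(rates)))
  B <- B[, -1, drop = FALSE]
  colnames(B) <- colnames(X)
  rownames(B) <- rownames(rates)
  attr(B, "n_trials") <- ncol(rates)
  B
}

#' Correlate two coefficient vectors across the population
#'
#' Pearson correlation between two per-neuron weight vectors, signed or
#' unsigned (absolute values). Reports the two-sided p, a Fisher-z 95% CI on
#' r, and the regression slope of `b` on `a` with its 95% CI. Neurons with a
#' missing weight in either vector are excluded pairwise.
#'
#' @param a,b Numeric per-neuron weight vectors (same neurons, same order).
#' @param mode `"signed"` or `"unsigned"`.
#' @param signature Optional label stored in the result.
#' @return List with `signature`, `mode`, `r`, `p`, `ci_lo`, `ci_hi`
#'   (Fisher-z CI on r), `slope`, `slope_lo`, `slope_hi`, `n_neurons`.
#' @export
signature_correlation <- function(a, b, mode = c("signed", "unsigned"),
                                  signature = NA_character_) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("coefficient vectors differ in length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3) stop("need >= 3 neurons with valid weights")
  if (mode == "unsigned") { a <- abs(a); b <- abs(b) }
  ct <- stats::cor.test(a, b, method = "pearson")
  r <- unname(ct$estimate)
  z <- atanh(min(1 - 1e-12, max(-1 + 1e-12, r)))
  se <- 1 / sqrt(n - 3)
  fit <- stats::lm(b ~ a)
  ci <- stats::confint(fit)["a", ]
  list(signature = signature, mode = mode, r = r, p = ct$p.value,
       ci_lo = tanh(z - 1.96 * se), ci_hi = tanh(z + 1.96 * se),
       slope = unname(stats::coef(fit)["a"]),
       slope_lo = unname(ci[1]), slope_hi = unname(ci[2]),
       n_neurons = n)
}

#' All choice-process signatures for one area
#'
#' Runs the three regression specifications (integration: epoch-1 rates on
#' offer-1 probability and magnitude; alignment: epoch-1 rates on offer-1 EV
#' and epoch-2 rates on offer-2 EV; inhibition: epoch-2 rates on both offer
#' EVs) and correlates the weight vectors in both signed and unsigned modes.
#'
#' When the two weights of a signature come from the same regression fit
#' (integration, inhibition), their OLS sampling errors are correlated
#' (correlation roughly minus the correlation of the regressors), which would
#' bias the population correlation away from zero even for untuned neurons.
#' Those signatures are therefore cross-fitted: the first weight is estimated
#' on the odd-numbered trials and the second on the even-numbered trials
#' (each half still fits the full regression), making the noise in the two
#' vectors independent so the null expectation is zero. Alignment already
#' uses two different epochs and is fitted on all trials.
#'
#' @param sts A [spike_train_set()].
#' @param trials A [trial_table()].
#' @param epochs Named epoch list containing `epoch1` and `epoch2`
#'   (default [default_epochs()]).
#' @param alpha Unused placeholder kept for interface symmetry.
#' @return data.frame with one row per (signature, mode).
#' @export
compute_signatures <- function(sts, trials, epochs = default_epochs(),
                               alpha = 0.05) {
  z1 <- epoch_rates(bin_spikes(sts, epochs$epoch1, trials), zscore = TRUE)
  z2 <- epoch_rates(bin_spikes(sts, epochs$epoch2, trials), zscore = TRUE)
  n_tr <- nrow(trials)
  odd <- seq(1, n_tr, by = 2)
  even <- seq(2, n_tr, by = 2)
  X_int <- data.frame(prob1 = trials$offer1_prob, mag1 = trials$offer1_mag)
  X_inh <- data.frame(ev1 = trials$ev1, ev2 = trials$ev2)
  half_fit <- function(z, X, idx, col)
    fit_value_regressions(z[, idx, drop = FALSE],
                          X[idx, , drop = FALSE])[, col]
  b_al1 <- fit_value_regressions(z1, data.frame(ev1 = trials$ev1))
  b_al2 <- fit_value_regressions(z2, data.frame(ev2 = trials$ev2))
  pairs <- list(
    integration = list(half_fit(z1, X_int, odd, "prob1"),
                       half_fit(z1, X_int, even, "mag1")),
    alignment = list(b_al1[, "ev1"], b_al2[, "ev2"]),
    inhibition = list(half_fit(z2, X_inh, odd, "ev1"),
                      half_fit(z2, X_inh, even, "ev2"))
  )
  rows <- list()
  for (sig in names(pairs)) for (mode in c("signed", "unsigned")) {
    res <- signature_correlation(pairs[[sig]][[1]], pairs[[sig]][[2]],
                                 mode = mode, signature = sig)
    rows[[paste(sig, mode)]] <- as.data.frame(res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
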