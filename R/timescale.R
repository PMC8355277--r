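# Intrinsic timescales: across-trial spike-count autocorrelation in the 2-s
# task-free window before offer 1, averaged per area and fitted with an
# exponential decay with offset, R(k*delta) = A * (exp(-k*delta/tau) + B).

#' Pre-trial spike-count autocorrelation
#'
#' Bins the 2-s window preceding offer 1 into `delta_ms` bins, computes the
#' across-trial Pearson correlation of counts for every ordered bin pair, and
#' averages pairs sharing a lag `k*delta = |i - j|`. Per-neuron curves are
#' averaged into one area curve with a standard error across neurons. Bin
#' pairs involving a zero-variance bin are skipped (their correlation is
#' undefined); neurons with no spikes in the window on any trial are
#' excluded and counted.
#'
#' @param sts A [spike_train_set()].
#' @param trials A [trial_table()].
#' @param window Pre-offer window in s (default `c(-2, 0)`).
#' @param delta_ms Bin width, ms (default 20).
#' @param max_lag_ms Largest lag, ms (default 720).
#' @return data.frame `(lag_ms, R, se)` with attributes `n_neurons`
#'   (contributing), `n_excluded` (silent neurons), and `per_neuron`
#'   (neurons x lags matrix of per-neuron curves).
#' @export
pretrial_autocorrelation <- function(sts, trials, window = c(-2, 0),
                                     delta_ms = 20, max_lag_ms = 720) {
  stopifnot(window[1] < window[2])
  dur <- round((window[2] - window[1]) * 1000)
  ep <- epoch("pretrial", "offer1", offset_ms = round(window[1] * 1000),
              duration_ms = dur, bin_width_ms = delta_ms)
  counts <- bin_spikes(sts, ep, trials)
  nn <- dim(counts)[1]; nb <- dim(counts)[3]
  if (dim(counts)[2] < 2) stop("need >= 2 trials per neuron")
  kmax <- min(nb - 1L, max_lag_ms %/% delta_ms)
  lags <- seq_len(kmax) * delta_ms
  silent <- rowSums(counts, dims = 1) == 0
  curves <- matrix(NA_real_, nn, kmax)
  for (i in which(!silent)) {
    cm <- suppressWarnings(stats::cor(counts[i, , ]))  # bins x bins
    for (k in seq_len(kmax)) {
      v <- cm[cbind(seq_len(nb - k), seq_len(nb - k) + k)]
      v <- v[is.finite(v)]
      if (length(v)) curves[i, k] <- mean(v)
    }
  }
  used <- !silent & rowSums(is.finite(curves)) > 0
  R <- colMeans(curves[used, , drop = FALSE], na.rm = TRUE)
  se <- apply(curves[used, , drop = FALSE], 2, function(x)
    stats::sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x))))
  out <- data.frame(lag_ms = lags, R = R, se = se)
  attr(out, "n_neurons") <- sum(used)
  attr(out, "n_excluded") <- sum(!used)
  attr(out, "per_neuron") <- curves
  out
}

#' Fit an exponential decay with offset to an autocorrelation curve
#'
#' Bounded nonlinear least squares of `R(k*delta) = A * (exp(-k*delta/tau) + B)`
#' with tau in [1, 5000] ms, A in [0, 2], B in [-1, 1], multi-started from
#' tau0 in {50, 100, 300, 600} ms (best SSE kept). A fit that fails, lands on
#' a parameter bound, or faces a flat curve is reported with
#' `converged = FALSE`; values are still returned.
#'
#' @param acf data.frame `(lag_ms, R)` from [pretrial_autocorrelation()].
#' @param tau_starts Initial timescales, ms.
#' @return List `(A, tau_ms, B, sse, converged)`.
#' @export
fit_exponential_decay <- function(acf, tau_starts = c(50, 100, 300, 600)) {
  stopifnot(all(c("lag_ms", "R") %in% names(acf)))
  d <- acf[is.finite(acf$R), c("lag_ms", "R")]
  if (nrow(d) < 4) stop("need >= 4 lag points to fit the decay model")
  lower <- c(A = 0, tau = 1, B = -1)
  upper <- c(A = 2, tau = 5000, B = 1)
  best <- NULL
  for (tau0 in tau_starts) {
    a0 <- max(d$R[1] - min(d$R), 1e-3)
    b0 <- min(max(min(d$R) / a0, -0.99), 0.99)
    fit <- tryCatch(
      minpack.lm::nlsLM(R ~ A * (exp(-lag_ms / tau) + B), data = d,
                        start = list(A = a0, tau = tau0, B = b0),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(A = unname(cf["A"]), tau_ms = unname(cf["tau"]),
                   B = unname(cf["B"]), sse = sse)
    }
  }
  if (is.null(best))
    return(list(A = NA_real_, tau_ms = NA_real_, B = NA_real_,
                sse = NA_real_, converged = FALSE))
  tol <- 1e-6
  on_bound <-
    best$A <= lower["A"] + tol * max(1, abs(lower["A"])) ||
    best$A >= upper["A"] - tol ||
    best$tau_ms <= lower["tau"] + tol ||
    best$tau_ms >= upper["tau"] - tol ||
    best$B <= lower["B"] + tol || best$B >= upper["B"] - tol
  flat <- stats::sd(d$R) < 1e-10 || best$A < 1e-8
  best$converged <- !(on_bound || flat)
  best
}

#' Cross-area timescale gradient test
#'
#' Pearson correlation of fitted intrinsic timescales against the gradient
#' order 1-4.
#'
#' @param taus Per-area fitted tau, ms.
#' @param order Gradient order indices (default `1:4`).
#' @param converged Optional logical per area; any `FALSE` is an error
#'   naming the offending areas.
#' @return List `(r, p)`.
#' @export
timescale_gradient <- function(taus, order = seq_along(taus),
                               converged = NULL) {
  if (!is.null(converged) && any(!converged))
    stop("unconverged timescale fit for area(s): ",
         paste(which(!converged), collapse = ", "))
  if (length(taus) != length(order) || length(taus) < 3)
    stop("need matched taus and order for >= 3 areas")
  if (stats::sd(taus) == 0)
    stop("timescales constant across areas; correlation undefined")
  ct <- stats::cor.test(taus, order, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Fit one area's intrinsic timescale end-to-end
#'
#' Convenience wrapper: pre-trial autocorrelation followed by the decay fit.
#'
#' @inheritParams pretrial_autocorrelation
#' @return List `(acf, fit)`.
#' @export
area_timescale <- function(sts, trials, window = c(-2, 0), delta_ms = 20,
                           max_lag_ms = 720) {
  acf <- pretrial_autocorrelation(sts, trials, window, delta_ms, max_lag_ms)
  list(acf = acf, fit = fit_exponential_decay(acf))
}
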