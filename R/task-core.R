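#' Expected value of a risky offer
#'
#' The expected value (EV) of an offer is the product of its reward
#' magnitude (in microlitres of juice) and its reward probability. EV is the
#' common currency every downstream analysis regresses or decodes against.
#'
#' @param magnitude Reward magnitude in uL; non-negative, vectorized.
#' @param probability Reward probability in `[0, 1]`; vectorized.
#' @return Expected value in uL (`magnitude * probability`).
#' @examples
#' expected_value(240, 0.5)  # 120
#' expected_value(125, 1.0)  # safe option
#' @export
expected_value <- function(magnitude, probability) {
  if (any(!is.finite(magnitude)) || any(magnitude < 0))
    stop("`magnitude` must be finite and non-negative")
  if (any(!is.finite(probability)) || any(probability < 0) || any(probability > 1))
    stop("`probability` must lie in [0, 1]")
  magnitude * probability
}

#' Define an analysis epoch
#'
#' An epoch is a half-open window `[anchor + offset, anchor + offset + duration)`
#' locked to a named trial event. Analysis epochs are 500 ms; the pre-trial
#' window used for baseline and timescale analyses is 2000 ms.
#'
#' @param name Epoch label.
#' @param anchor One of `"offer1"`, `"offer2"`, `"choice"` — the trial-table
#'   event time the window is locked to.
#' @param offset_ms Window start relative to the anchor, ms.
#' @param duration_ms Window length, ms; must be a positive multiple of
#'   `bin_width_ms`.
#' @param bin_width_ms Bin width used when the epoch is discretized (default 20).
#' @return An object of class `"epoch"`.
#' @export
epoch <- function(name, anchor, offset_ms, duration_ms, bin_width_ms = 20) {
  anchor <- match.arg(anchor, c("offer1", "offer2", "choice"))
  stopifnot(is.numeric(offset_ms), length(offset_ms) == 1L, is.finite(offset_ms))
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("`duration_ms` must be positive")
  if (duration_ms %% bin_width_ms != 0)
    stop("`duration_ms` must be a positive multiple of `bin_width_ms`")
  structure(list(name = name, anchor = anchor, offset_ms = offset_ms,
                 duration_ms = duration_ms, bin_width_ms = bin_width_ms),
            class = "epoch")
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch '%s': %s %+d to %+d ms, %d-ms bins>\n",
              x$name, x$anchor, x$offset_ms, x$offset_ms + x$duration_ms,
              x$bin_width_ms))
  invisible(x)
}

#' Default analysis epochs
#'
#' The trial divides into four 500-ms analysis epochs (offer 1, offer 2,
#' choice, post-choice) plus the 2-s pre-trial window. Offer epochs start at
#' the corresponding offer onset; the choice epoch starts at choice fixation;
#' the post-choice epoch follows the choice epoch.
#'
#' @param bin_width_ms Bin width in ms (default 20).
#' @return Named list of [epoch()] objects:
#'   `pretrial`, `epoch1`, `epoch2`, `choice`, `postchoice`.
#' @export
default_epochs <- function(bin_width_ms = 20) {
  list(
    pretrial   = epoch("pretrial",   "offer1", -2000, 2000, bin_width_ms),
    epoch1     = epoch("epoch1",     "offer1",     0,  500, bin_width_ms),
    epoch2     = epoch("epoch2",     "offer2",     0,  500, bin_width_ms),
    choice     = epoch("choice",     "choice",     0,  500, bin_width_ms),
    postchoice = epoch("postchoice", "choice",   500,  500, bin_width_ms)
  )
}

anchor_times <- function(trials, anchor) {
  col <- switch(anchor, offer1 = "t_offer1", offer2 = "t_offer2",
                choice = "t_choice")
  trials[[col]]
}

trial_table_columns <- c(
  "trial_id", "offer1_mag", "offer1_prob", "offer1_side",
  "offer2_mag", "offer2_prob", "offer2_side", "ev1", "ev2",
  "chosen_offer", "chosen_side", "rewarded",
  "prev_chosen_offer", "prev_rewarded",
  "t_offer1", "t_offer2", "t_choice"
)

#' Validate a trial table
#'
#' Checks the per-trial task table: required columns, EV consistency
#' (`ev = mag * prob`), probabilities in `[0, 1]`, complementary offer sides,
#' and previous-trial lag consistency (`prev_*` of trial k equals the
#' chosen/rewarded fields of trial k-1; `NA` on the first trial).
#'
#' @param trials A data.frame with one row per trial. Times are in seconds
#'   relative to offer-1 onset (`t_offer1` is 0 by convention).
#' @return The validated table, classed `"trial_table"`.
#' @export
trial_table <- function(trials) {
  missing_cols <- setdiff(trial_table_columns, names(trials))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  with(trials, {
    if (any(offer1_prob < 0 | offer1_prob > 1 | offer2_prob < 0 | offer2_prob > 1))
      stop("offer probabilities must lie in [0, 1]")
    if (any(abs(ev1 - offer1_mag * offer1_prob) > 1e-8) ||
        any(abs(ev2 - offer2_mag * offer2_prob) > 1e-8))
      stop("ev columns inconsistent with magnitude x probability")
    if (any(offer1_side == offer2_side))
      stop("offer sides must be complementary within a trial")
    if (!all(chosen_offer %in% c(1L, 2L)))
      stop("chosen_offer must be 1 or 2")
  })
  n <- nrow(trials)
  if (n > 1L) {
    lag_choice <- trials$chosen_offer[-n]
    lag_reward <- trials$rewarded[-n]
    pc <- trials$prev_chosen_offer[-1L]
    pr <- trials$prev_rewarded[-1L]
    ok <- (is.na(pc) & is.na(pr)) | (pc == lag_choice & pr == lag_reward)
    if (any(!ok, na.rm = TRUE) || any(is.na(ok)))
      stop("prev_* fields inconsistent with preceding trial")
  }
  class(trials) <- unique(c("trial_table", class(trials)))
  trials
}

#' Construct a spike-train set
#'
#' Container for sorted spike times per (neuron, trial), aligned to offer-1
#' onset. Every (neuron, trial) pair is considered present; pairs without
#' spikes are simply absent from the long table. The recorded span must
#' include at least 2 s before offer 1 on every trial (required by the
#' baseline and intrinsic-timescale analyses).
#'
#' @param spikes data.frame with columns `neuron_id`, `trial_id`,
#'   `spike_time_s` (seconds relative to offer-1 onset).
#' @param neuron_ids Integer vector of all neuron ids (including silent ones).
#' @param trial_ids Integer vector of all trial ids.
#' @param span Numeric length-2: recorded window `[t_min, t_max]` in s,
#'   common to all trials.
#' @return An object of class `"spike_train_set"`.
#' @export
spike_train_set <- function(spikes, neuron_ids, trial_ids, span) {
  stopifnot(all(c("neuron_id", "trial_id", "spike_time_s") %in% names(spikes)),
            length(span) == 2L, span[1] < span[2])
  neuron_ids <- sort(unique(as.integer(neuron_ids)))
  trial_ids <- sort(unique(as.integer(trial_ids)))
  if (nrow(spikes)) {
    if (!all(spikes$neuron_id %in% neuron_ids))
      stop("spikes reference unknown neuron_id")
    if (!all(spikes$trial_id %in% trial_ids))
      stop("spikes reference unknown trial_id")
    if (any(spikes$spike_time_s < span[1] | spikes$spike_time_s > span[2]))
      stop("spike times outside the recorded span")
    o <- order(spikes$neuron_id, spikes$trial_id, spikes$spike_time_s)
    spikes <- spikes[o, c("neuron_id", "trial_id", "spike_time_s")]
    rownames(spikes) <- NULL
  }
  structure(list(spikes = spikes, neuron_ids = neuron_ids,
                 trial_ids = trial_ids, span = as.numeric(span)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set: %d neurons x %d trials, %d spikes, span [%.2f, %.2f] s>\n",
              length(x$neuron_ids), length(x$trial_ids), nrow(x$spikes),
              x$span[1], x$span[2]))
  invisible(x)
}

#' Bin spikes within an epoch
#'
#' Counts spikes in fixed-width bins tiling one epoch on every trial. Bins
#' are half-open `[start + w*b, start + w*(b+1))`: a spike exactly on a bin's
#' right edge belongs to the next bin, and a spike exactly at the epoch end
#' is excluded. Total counts are conserved (sum over bins equals the number
#' of spikes in the window).
#'
#' @param sts A [spike_train_set()].
#' @param ep An [epoch()].
#' @param trials A [trial_table()] supplying the anchor event times.
#' @return A 3-d integer array `neurons x trials x bins` (spike counts per
#'   bin) with attributes `neuron_ids`, `trial_ids`, `epoch`, and
#'   `bin_width_ms`. Dimnames carry the ids.
#' @export
bin_spikes <- function(sts, ep, trials) {
  stopifnot(inherits(sts, "spike_train_set"), inherits(ep, "epoch"))
  tid <- sts$trial_ids
  tt <- trials[match(tid, trials$trial_id), , drop = FALSE]
  if (any(is.na(tt$trial_id)))
    stop("trial table lacks trials present in the spike set: ",
         paste(utils::head(tid[is.na(tt$trial_id)], 5), collapse = ", "))
  anchor <- anchor_times(tt, ep$anchor)
  w0 <- anchor + ep$offset_ms / 1000
  w1 <- w0 + ep$duration_ms / 1000
  bad <- which(w0 < sts$span[1] - 1e-9 | w1 > sts$span[2] + 1e-9)
  if (length(bad))
    stop("epoch '", ep$name, "' outside recorded span on trials: ",
         paste(utils::head(tid[bad], 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  nb <- ep$duration_ms %/% ep$bin_width_ms
  nn <- length(sts$neuron_ids)
  nt <- length(tid)
  counts <- array(0L, dim = c(nn, nt, nb),
                  dimnames = list(sts$neuron_ids, tid, NULL))
  sp <- sts$spikes
  if (nrow(sp)) {
    ti <- match(sp$trial_id, tid)
    rel_ms <- (sp$spike_time_s - anchor[ti]) * 1000 - ep$offset_ms
    b <- floor(rel_ms / ep$bin_width_ms)
    keep <- b >= 0 & b < nb
    if (any(keep)) {
      ni <- match(sp$neuron_id[keep], sts$neuron_ids)
      idx <- (as.numeric(b[keep]) * nt + (ti[keep] - 1)) * nn + ni
      tab <- tabulate(idx, nbins = nn * nt * nb)
      counts[] <- as.integer(tab)
    }
  }
  attr(counts, "neuron_ids") <- sts$neuron_ids
  attr(counts, "trial_ids") <- tid
  attr(counts, "epoch") <- ep
  attr(counts, "bin_width_ms") <- ep$bin_width_ms
  counts
}

#' Mean firing rates within an epoch
#'
#' Reduces a binned count tensor to one mean rate per neuron and trial
#' (total count / epoch duration, spikes/s), optionally z-scored per neuron
#' across trials. Neurons with zero across-trial variance get z = 0 and are
#' flagged rather than dropped, so population matrices keep a stable shape.
#'
#' @param counts Count tensor from [bin_spikes()].
#' @param zscore Standardize each neuron across trials (default `FALSE`).
#' @return `neurons x trials` numeric matrix of rates (spikes/s) with
#'   attributes `epoch` and, when `zscore = TRUE`, a logical
#'   `zero_variance` flag per neuron plus per-neuron `center`/`scale`.
#' @export
epoch_rates <- function(counts, zscore = FALSE) {
  ep <- attr(counts, "epoch")
  stopifnot(!is.null(ep))
  dur_s <- ep$duration_ms / 1000
  rates <- rowSums(counts, dims = 2) / dur_s
  dimnames(rates) <- dimnames(counts)[1:2]
  attr(rates, "epoch") <- ep
  if (zscore) {
    mu <- rowMeans(rates)
    sdv <- apply(rates, 1, stats::sd)
    zero_var <- !is.finite(sdv) | sdv == 0
    sc <- ifelse(zero_var, 1, sdv)
    z <- (rates - mu) / sc
    z[zero_var, ] <- 0
    attr(z, "epoch") <- ep
    attr(z, "zero_variance") <- zero_var
    attr(z, "center") <- mu
    attr(z, "scale") <- sc
    return(z)
  }
  rates
}

#' Read / write the standard CSV interchange formats
#'
#' The trial table is one row per trial with exactly the documented columns;
#' spikes are long-format `(session_id, neuron_id, trial_id, spike_time_s)`.
#'
#' @param path File path.
#' @param trials,sts Objects to write.
#' @param session_id Session tag written with the spikes.
#' @param span Recorded span passed through to [spike_train_set()] on read.
#' @return `read_trials` returns a [trial_table()]; `read_spikes` a
#'   [spike_train_set()].
#' @name task_io
NULL

#' @rdname task_io
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$rewarded <- as.logical(df$rewarded)
  df$prev_rewarded <- as.logical(df$prev_rewarded)
  trial_table(df)
}

#' @rdname task_io
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials)[, trial_table_columns], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname task_io
#' @export
read_spikes <- function(path, span, session_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(session_id) && "session_id" %in% names(df))
    df <- df[df$session_id == session_id, , drop = FALSE]
  spike_train_set(df[, c("neuron_id", "trial_id", "spike_time_s")],
                  neuron_ids = unique(df$neuron_id),
                  trial_ids = unique(df$trial_id), span = span)
}

#' @rdname task_io
#' @export
write_spikes <- function(sts, path, session_id = 1L) {
  df <- cbind(session_id = session_id, sts$spikes)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Boxcar-smooth a time course for display
#'
#' Plotting helper mirroring the usual 200-ms running-boxcar smoothing of
#' peri-stimulus time histograms. Analysis functions never smooth.
#'
#' @param x Numeric vector sampled on a regular grid.
#' @param width_ms Boxcar width, ms (default 200).
#' @param bin_width_ms Sample spacing, ms (default 20).
#' @return Smoothed vector of the same length (edges use shrinking windows).
#' @export
boxcar_smooth <- function(x, width_ms = 200, bin_width_ms = 20) {
  k <- max(1L, round(width_ms / bin_width_ms))
  n <- length(x)
  half <- k %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}
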