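# Pseudo-population decoding: per-neuron trial resampling into label-matched
# pseudo-trials (destroying noise correlations by construction), a linear
# SVM trained on half the pseudo-trials and tested on the held-out half,
# shuffle nulls, a 12-label decoding battery with decimation and multinomial
# EV controls, and cross-area gradient-order rank tests.

#' The twelve decoder label/epoch pairs
#'
#' Ten binary task labels, two of which (offer-1 value and chosen side) are
#' decoded in two epochs each. Continuous value labels are binarized by a
#' mean split (value greater than the across-trial mean; ties go to the low
#' class); categorical labels are used directly.
#'
#' @return data.frame `(name, epoch, description)`.
#' @export
decoder_label_specs <- function() {
  data.frame(
    name = c("ev1_epoch1", "ev1_epoch2", "ev2_epoch2", "ev_diff_epoch2",
             "offer1_side_epoch1", "choice_epoch", "chosen_side_choice",
             "chosen_value_choice", "unchosen_value_choice",
             "prev_choice_choice", "prev_reward_choice",
             "chosen_side_postchoice"),
    epoch = c("epoch1", "epoch2", "epoch2", "epoch2", "epoch1", "choice",
              "choice", "choice", "choice", "choice", "choice", "postchoice"),
    description = c(
      "offer-1 EV above mean, offer-1 epoch",
      "offer-1 EV above mean, offer-2 epoch (value working memory)",
      "offer-2 EV above mean, offer-2 epoch",
      "EV difference (ev1 - ev2) above mean, offer-2 epoch",
      "offer 1 on the left, offer-1 epoch",
      "chose offer 1, choice epoch",
      "chosen side left, choice epoch",
      "chosen-offer EV above mean, choice epoch",
      "unchosen-offer EV above mean, choice epoch",
      "previous trial chose offer 1, choice epoch",
      "previous trial rewarded, choice epoch",
      "chosen side left, post-choice epoch"),
    stringsAsFactors = FALSE
  )
}

# Binary label vector for one spec; NA marks trials excluded (first-trial
# lags). Mean-split ties are assigned to the low class.
make_decoder_label <- function(trials, name) {
  mean_split <- function(x) x > mean(x)
  chosen_ev <- ifelse(trials$chosen_offer == 1L, trials$ev1, trials$ev2)
  unchosen_ev <- ifelse(trials$chosen_offer == 1L, trials$ev2, trials$ev1)
  switch(name,
    ev1_epoch1 = ,
    ev1_epoch2 = mean_split(trials$ev1),
    ev2_epoch2 = mean_split(trials$ev2),
    ev_diff_epoch2 = mean_split(trials$ev1 - trials$ev2),
    offer1_side_epoch1 = trials$offer1_side == "left",
    choice_epoch = trials$chosen_offer == 1L,
    chosen_side_choice = ,
    chosen_side_postchoice = trials$chosen_side == "left",
    chosen_value_choice = mean_split(chosen_ev),
    unchosen_value_choice = mean_split(unchosen_ev),
    prev_choice_choice = trials$prev_chosen_offer == 1L,
    prev_reward_choice = trials$prev_rewarded,
    stop("unknown decoder label: ", name)
  )
}

#' Build a pseudo-population
#'
#' For each neuron and label level, records the pool of that neuron's
#' single-trial rates; pseudo-trials are later drawn from these pools with
#' replacement, independently across neurons. Trials with a missing label
#' are dropped. Neurons lacking trials at either level are excluded (with a
#' report); more than `max_excluded` of the population missing is an error.
#'
#' @param rates `neurons x trials` rate matrix.
#' @param labels Logical per-trial label (NA allowed).
#' @param n_pseudotrials Pseudo-trials per class (default 1000).
#' @param max_excluded Largest tolerated excluded fraction (default 0.2).
#' @return A `"pseudo_population"` object.
#' @export
build_pseudopopulation <- function(rates, labels, n_pseudotrials = 1000,
                                   max_excluded = 0.2) {
  stopifnot(is.matrix(rates), ncol(rates) == length(labels))
  keep_tr <- !is.na(labels)
  rates <- rates[, keep_tr, drop = FALSE]
  labels <- labels[keep_tr]
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("label must have exactly two observed levels")
  idx0 <- which(!labels); idx1 <- which(labels)
  # every neuron shares the trial set, so exclusion only occurs when a class
  # is empty overall; kept per-neuron for interface stability with ragged data
  excluded <- integer(0)
  if (length(idx0) == 0 || length(idx1) == 0)
    stop("a label level has no trials")
  structure(list(rates = rates, idx0 = idx0, idx1 = idx1,
                 n_pseudotrials = as.integer(n_pseudotrials),
                 n_neurons = nrow(rates), excluded = excluded),
            class = "pseudo_population")
}

#' Draw one pseudo-trial realization
#'
#' Samples `n_pseudotrials` rates per neuron and class from the pools, with
#' replacement and independently across neurons.
#'
#' @param pp A [build_pseudopopulation()] object.
#' @return List of two `neurons x n_pseudotrials` matrices (`low`, `high`).
#' @export
draw_pseudotrials <- function(pp) {
  n <- pp$n_neurons; P <- pp$n_pseudotrials
  draw <- function(idx) {
    ridx <- sample(idx, n * P, replace = TRUE)
    matrix(pp$rates[cbind(rep(seq_len(n), P), ridx)], n, P)
  }
  list(low = draw(pp$idx0), high = draw(pp$idx1))
}

# One train/test round: split each class's pseudo-trials in half, z-score
# features on training statistics only, fit a linear SVM (C = 1), return
# held-out accuracy. `shuffle` permutes class labels across all pseudo-trials
# before the split.
svm_round <- function(m, shuffle = FALSE) {
  P <- ncol(m$low)
  half <- P %/% 2
  X <- t(cbind(m$low, m$high))      # 2P x neurons
  y <- rep(c(0L, 1L), each = P)
  if (shuffle) y <- sample(y)
  s0 <- sample.int(P, half); s1 <- P + sample.int(P, half)
  tr <- c(s0, s1); te <- setdiff(seq_len(2L * P), tr)
  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  ytr <- factor(y[tr], levels = c(0L, 1L))
  if (length(unique(y[tr])) < 2) return(NA_real_)
  fit <- e1071::svm(Xs[tr, , drop = FALSE], ytr, kernel = "linear", cost = 1,
                    scale = FALSE)
  pred <- stats::predict(fit, Xs[te, , drop = FALSE])
  mean(as.integer(as.character(pred)) == y[te])
}

#' Cross-validated pseudo-population decoding of one binary label
#'
#' Per repeat: redraw the pseudo-trials, split each class in half, train a
#' linear support vector machine on one half-pair and test on the other.
#' The shuffle control repeats the identical procedure with class labels
#' permuted. Train and test pseudo-trial indices are disjoint within every
#' repeat.
#'
#' @param pp A [build_pseudopopulation()] object.
#' @param n_reps Cross-validation repeats (default 1000).
#' @param seed Master seed; each repeat consumes its own substream.
#' @param shuffle Also run the shuffle control (default `TRUE`).
#' @param label Optional label name stored in the result.
#' @return A `"decoder_result"` list: `accuracies`, `shuffle_accuracies`,
#'   `mean`, `se`, `shuffle_mean`, `n_reps`, `n_neurons`, `degenerate`.
#' @export
decode_label <- function(pp, n_reps = 1000, seed = 1L, shuffle = TRUE,
                         label = NA_character_) {
  stopifnot(inherits(pp, "pseudo_population"))
  pooled_sd <- stats::sd(pp$rates)
  degenerate <- !is.finite(pooled_sd) || pooled_sd == 0
  acc <- numeric(n_reps)
  sh <- if (shuffle) numeric(n_reps) else NULL
  for (r in seq_len(n_reps)) {
    set.seed(substream_seed(seed, paste0(label, "-rep-", r)))
    m <- draw_pseudotrials(pp)
    acc[r] <- svm_round(m, shuffle = FALSE)
    if (shuffle) sh[r] <- svm_round(m, shuffle = TRUE)
  }
  structure(list(label = label, accuracies = acc, shuffle_accuracies = sh,
                 mean = mean(acc), se = stats::sd(acc) / sqrt(n_reps),
                 shuffle_mean = if (shuffle) mean(sh) else NA_real_,
                 n_reps = n_reps, n_neurons = pp$n_neurons,
                 degenerate = degenerate),
            class = "decoder_result")
}

#' Run the twelve-decoder battery on one area
#'
#' Computes epoch-mean rates for every epoch a label needs, builds the
#' pseudo-population per label, and decodes. Optional controls: decimation
#' subsamples the population to a fixed neuron count (without replacement,
#' seeded) before decoding; the multinomial control discretizes EV into six
#' consecutive bins and fits a multiclass classifier (see
#' [multinomial_ev_decoder()]). Labels with a single observed level are
#' skipped with a report.
#'
#' @param dataset One area dataset: list with `area`, `order_index`,
#'   `trials`, `spikes` (as from [generate_gradient_dataset()]).
#' @param specs Label table (default [decoder_label_specs()]).
#' @param epochs Epoch list (default [default_epochs()]).
#' @param n_pseudotrials,n_reps Sizes per decoder.
#' @param seed Master seed.
#' @param shuffle Run shuffle controls.
#' @param decimate_to If non-NULL, decode on this many randomly chosen
#'   neurons instead of the full population.
#' @return List with `table` (one row per label: area, label, epoch,
#'   mean_acc, se, shuffle_mean, n_reps, n_neurons, degenerate, decimated),
#'   `results` (the `decoder_result` objects), and `skipped`.
#' @export
decoder_battery <- function(dataset, specs = decoder_label_specs(),
                            epochs = default_epochs(),
                            n_pseudotrials = 1000, n_reps = 1000,
                            seed = 1L, shuffle = TRUE, decimate_to = NULL) {
  trials <- dataset$trials
  keep_neurons <- dataset$spikes$neuron_ids
  if (!is.null(decimate_to)) {
    if (decimate_to > length(keep_neurons))
      stop("cannot decimate to more neurons than recorded")
    set.seed(substream_seed(seed, paste0("decimate-", dataset$area)))
    keep_neurons <- sort(sample(keep_neurons, decimate_to))
  }
  rate_cache <- list()
  area_rates <- function(ep_name) {
    if (is.null(rate_cache[[ep_name]])) {
      r <- epoch_rates(bin_spikes(dataset$spikes, epochs[[ep_name]], trials))
      rate_cache[[ep_name]] <<- r[match(keep_neurons, as.integer(rownames(r))),
                                  , drop = FALSE]
    }
    rate_cache[[ep_name]]
  }
  results <- list(); skipped <- character(0); rows <- list()
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]; epn <- specs$epoch[i]
    lab <- make_decoder_label(trials, nm)
    obs <- unique(lab[!is.na(lab)])
    if (length(obs) < 2) { skipped <- c(skipped, nm); next }
    pp <- build_pseudopopulation(area_rates(epn), lab, n_pseudotrials)
    res <- decode_label(pp, n_reps = n_reps,
                        seed = substream_seed(seed, paste0(dataset$area, "-", nm)),
                        shuffle = shuffle, label = nm)
    results[[nm]] <- res
    rows[[nm]] <- data.frame(area = dataset$area,
                             order_index = dataset$order_index,
                             label = nm, epoch = epn,
                             mean_acc = res$mean, se = res$se,
                             shuffle_mean = res$shuffle_mean,
                             n_reps = n_reps, n_neurons = res$n_neurons,
                             degenerate = res$degenerate,
                             decimated = !is.null(decimate_to))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, results = results, skipped = skipped)
}

#' Multinomial expected-value decoding control
#'
#' Discretizes EV into six consecutive bins (quantile bins by default, so
#' every class keeps a usable trial count; equal-width optional), builds a
#' six-class pseudo-population, and fits a multiclass linear classifier
#' (multinomial logistic regression by default, or a linear-kernel
#' multiclass SVM), reporting held-out per-class and overall accuracy.
#'
#' @param rates `neurons x trials` rate matrix.
#' @param ev Per-trial expected value.
#' @param n_bins Number of EV classes (default 6).
#' @param binning `"quantile"` (default) or `"width"`.
#' @param n_pseudotrials Pseudo-trials per class (default 200).
#' @param n_reps Repeats (default 100).
#' @param method `"multinom"` or `"svm"`.
#' @param seed Master seed.
#' @return List `(overall, per_class, accuracies, n_bins)`.
#' @export
multinomial_ev_decoder <- function(rates, ev, n_bins = 6,
                                   binning = c("quantile", "width"),
                                   n_pseudotrials = 200, n_reps = 100,
                                   method = c("multinom", "svm"), seed = 1L) {
  binning <- match.arg(binning); method <- match.arg(method)
  brks <- if (binning == "quantile")
    unique(stats::quantile(ev, probs = seq(0, 1, length.out = n_bins + 1)))
  else seq(min(ev), max(ev), length.out = n_bins + 1)
  cls <- cut(ev, breaks = brks, include.lowest = TRUE, labels = FALSE)
  k <- length(unique(cls))
  pools <- lapply(seq_len(k), function(c) which(cls == c))
  if (any(lengths(pools) == 0)) stop("an EV bin has no trials")
  n <- nrow(rates); P <- n_pseudotrials; half <- P %/% 2
  acc <- numeric(n_reps)
  per_class <- matrix(NA_real_, n_reps, k)
  for (r in seq_len(n_reps)) {
    set.seed(substream_seed(seed, paste0("mnl-rep-", r)))
    mats <- lapply(pools, function(idx) {
      ridx <- sample(idx, n * P, replace = TRUE)
      matrix(rates[cbind(rep(seq_len(n), P), ridx)], n, P)
    })
    tr_cols <- lapply(seq_len(k), function(c) sample.int(P, half))
    Xtr <- do.call(rbind, lapply(seq_len(k), function(c)
      t(mats[[c]][, tr_cols[[c]], drop = FALSE])))
    Xte <- do.call(rbind, lapply(seq_len(k), function(c)
      t(mats[[c]][, -tr_cols[[c]], drop = FALSE])))
    ytr <- factor(rep(seq_len(k), each = half))
    yte <- factor(rep(seq_len(k), each = P - half))
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    pred <- if (method == "multinom") {
      fit <- nnet::multinom(y ~ ., data = data.frame(y = ytr, Xtr),
                            trace = FALSE, MaxNWts = 1e6)
      stats::predict(fit, newdata = data.frame(Xte))
    } else {
      fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = 1, scale = FALSE)
      stats::predict(fit, Xte)
    }
    acc[r] <- mean(pred == yte)
    per_class[r, ] <- vapply(seq_len(k), function(c)
      mean(pred[yte == c] == c), numeric(1))
  }
  list(overall = mean(acc), per_class = colMeans(per_class),
       accuracies = acc, n_bins = k)
}

#' Cross-area gradient-order test
#'
#' Spearman rank correlation of a per-area statistic against the gradient
#' order 1-4. In scalar mode, four values are correlated with the order; in
#' distribution mode, every repeat's value is pooled and ranked against its
#' area's order label (the way decoding-accuracy distributions are tested).
#'
#' @param values Either a numeric vector (one value per area) or a list of
#'   numeric vectors (one distribution per area).
#' @param order Gradient order indices, same length as `values`.
#' @return List `(rho, p, mode)`.
#' @export
gradient_order_test <- function(values, order = seq_along(values)) {
  if (is.list(values)) {
    stopifnot(length(values) == length(order))
    x <- unlist(values, use.names = FALSE)
    g <- rep(order, lengths(values))
    mode <- "distribution"
  } else {
    x <- as.numeric(values); g <- order
    mode <- "scalar"
  }
  if (length(unique(x)) < 2)
    stop("all values tied; Spearman correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, g, method = "spearman",
                    exact = (mode == "scalar" && length(x) <= 10)))
  list(rho = unname(ct$estimate), p = ct$p.value, mode = mode)
}
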