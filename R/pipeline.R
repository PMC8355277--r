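# Orchestration: configuration, seeding, end-to-end runs, and a
# machine-readable report joining every stage's outputs with the
# cross-area gradient-order tests.

#' Default pipeline configuration
#'
#' Sizes default to the full study conditions (four areas with the recorded
#' population counts, 500 trials per session, 1000 pseudo-trials and 1000
#' repeats per decoder). Analyses can be scaled down through the config for
#' quick runs.
#'
#' @return Nested configuration list with sections `task`, `areas`,
#'   `epochs`, `selectivity`, `timescale`, `decoding`, `seed`.
#' @export
default_config <- function() {
  list(
    task = list(n_trials = 500,
                behavior = list(beta = 0.0264, side_bias = 0)),
    areas = lapply(default_gradient_spec(), function(a)
      list(name = a$name, order_index = a$order_index,
           n_neurons = a$n_neurons, snr_scale = a$snr_scale,
           ou_tau_mean_ms = a$ou_tau_mean_ms)),
    epochs = list(bin_width_ms = 20),
    selectivity = list(alpha = 0.05, null_rate = 0.05,
                       run_timecourse = FALSE),
    timescale = list(delta_ms = 20, max_lag_ms = 720),
    decoding = list(n_pseudotrials = 1000, n_reps = 1000, shuffle = TRUE,
                    decimate_to = 125, run_decimation = TRUE,
                    run_multinomial = FALSE,
                    multinomial = list(n_bins = 6, binning = "quantile",
                                       n_pseudotrials = 200, n_reps = 50)),
    seed = 1L
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

config_areas <- function(config) {
  lapply(config$areas, function(a)
    area_spec(a$name, a$order_index, a$n_neurons,
              snr_scale = if (is.null(a$snr_scale)) 1 else a$snr_scale,
              ou_tau_mean_ms = if (is.null(a$ou_tau_mean_ms)) 200
                               else a$ou_tau_mean_ms))
}

# FNV-1a hash of the canonical YAML text, for provenance.
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(config))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Load a dataset written by the simulate interface
#'
#' Reads `trials_<area>.csv` and `spikes_<area>.csv` for every configured
#' area from a directory.
#'
#' @param dir Input directory.
#' @param config Configuration naming the areas.
#' @return List of area datasets.
#' @export
load_dataset <- function(dir, config = default_config()) {
  tm <- task_timing()
  lapply(config$areas, function(a) {
    tp <- file.path(dir, paste0("trials_", a$name, ".csv"))
    sp <- file.path(dir, paste0("spikes_", a$name, ".csv"))
    for (p in c(tp, sp)) if (!file.exists(p)) stop("missing input file: ", p)
    trials <- read_trials(tp)
    list(area = a$name, order_index = a$order_index, trials = trials,
         spikes = read_spikes(sp, span = tm$span), neurons = NULL)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the four-area dataset, then runs every stage:
#' behavioural summary, per-neuron selectivity with population binomial
#' tests, offer-latency ANOVA, choice-process signatures, intrinsic
#' timescales with the Pearson gradient test, the decoding battery with
#' Spearman gradient tests (scalar per label on mean accuracies, plus the
#' pooled-distribution test on battery means), and the intrinsic-property
#' controls with their gradient tests. Deterministic under a fixed seed.
#'
#' @param config Configuration list (default [default_config()]).
#' @param seed Master seed (default `config$seed`).
#' @param datasets Optional pre-built list of area datasets (e.g. from
#'   [generate_gradient_dataset()] or [load_dataset()]); when `NULL`, data
#'   are simulated from the config.
#' @param out_dir If non-NULL, artifacts are written there via
#'   [write_report()].
#' @return A `"run_report"` list.
#' @export
run_pipeline <- function(config = default_config(), seed = config$seed,
                         datasets = NULL, out_dir = NULL) {
  epochs <- default_epochs(config$epochs$bin_width_ms)
  if (is.null(datasets)) {
    beh <- behavior_spec(config$task$behavior$beta,
                         config$task$behavior$side_bias)
    datasets <- generate_gradient_dataset(config_areas(config),
                                          n_trials = config$task$n_trials,
                                          behavior = beh, seed = seed)
  }
  areas <- vapply(datasets, `[[`, character(1), "area")
  orders <- vapply(datasets, `[[`, integer(1), "order_index")
  alpha <- config$selectivity$alpha

  behavior <- behavior_summary(lapply(datasets, `[[`, "trials"))

  # --- selectivity ---------------------------------------------------------
  tuning_rows <- list(); latency_rows <- list()
  for (d in datasets) {
    r1 <- epoch_rates(bin_spikes(d$spikes, epochs$epoch1, d$trials))
    r2 <- epoch_rates(bin_spikes(d$spikes, epochs$epoch2, d$trials))
    combos <- list(
      list(var = "ev1", epoch = "epoch1", rates = r1, values = d$trials$ev1),
      list(var = "ev2", epoch = "epoch2", rates = r2, values = d$trials$ev2),
      list(var = "ev1", epoch = "epoch2", rates = r2, values = d$trials$ev1))
    for (cb in combos) {
      tun <- value_tuning(cb$rates, cb$values, alpha)
      pop <- population_selectivity(tun, config$selectivity$null_rate)
      tuning_rows[[paste(d$area, cb$var, cb$epoch)]] <- data.frame(
        area = d$area, order_index = d$order_index, variable = cb$var,
        epoch = cb$epoch, n = pop$n, k = pop$k,
        proportion = pop$proportion, binomial_p = pop$p_value,
        mean_r2 = mean(tun$r2, na.rm = TRUE))
    }
    for (off in c(1, 2)) {
      ep <- if (off == 1) epochs$epoch1 else epochs$epoch2
      lat <- response_latency(bin_spikes(d$spikes, ep, d$trials), "peak")
      lat$area <- d$area; lat$offer <- off
      latency_rows[[paste(d$area, off)]] <- lat
    }
  }
  tuning <- do.call(rbind, tuning_rows); rownames(tuning) <- NULL
  latency <- do.call(rbind, latency_rows); rownames(latency) <- NULL
  lat_anova <- latency_anova(latency)
  lat_means <- stats::aggregate(latency_ms ~ area + offer, latency, mean)

  signatures <- do.call(rbind, lapply(datasets, function(d) {
    s <- compute_signatures(d$spikes, d$trials, epochs)
    cbind(area = d$area, order_index = d$order_index, s)
  }))
  rownames(signatures) <- NULL

  # --- intrinsic timescales ------------------------------------------------
  ts <- lapply(datasets, function(d)
    area_timescale(d$spikes, d$trials, delta_ms = config$timescale$delta_ms,
                   max_lag_ms = config$timescale$max_lag_ms))
  acf_tab <- do.call(rbind, Map(function(t, a) cbind(area = a, t$acf),
                                ts, areas))
  fits <- Map(function(t, a) c(list(area = a), t$fit), ts, areas)
  taus <- vapply(ts, function(t) t$fit$tau_ms, numeric(1))
  conv <- vapply(ts, function(t) t$fit$converged, logical(1))
  failures <- list()
  tau_gradient <- tryCatch(timescale_gradient(taus, orders, conv),
                           error = function(e) {
                             failures[["tau_gradient"]] <<- conditionMessage(e)
                             NULL
                           })

  # --- decoding battery ----------------------------------------------------
  dec <- config$decoding
  batteries <- lapply(datasets, decoder_battery, epochs = epochs,
                      n_pseudotrials = dec$n_pseudotrials,
                      n_reps = dec$n_reps, seed = seed,
                      shuffle = dec$shuffle)
  decoding <- do.call(rbind, lapply(batteries, `[[`, "table"))
  rownames(decoding) <- NULL
  gradient_rows <- list()
  if (!is.null(tau_gradient))
    gradient_rows[["timescale"]] <- data.frame(
      statistic = "timescale_tau", rho = tau_gradient$r, p = tau_gradient$p,
      mode = "pearson")
  for (lab in unique(decoding$label)) {
    sub <- decoding[decoding$label == lab, ]
    sub <- sub[order(sub$order_index), ]
    gt <- gradient_order_test(sub$mean_acc, sub$order_index)
    gradient_rows[[lab]] <- data.frame(statistic = paste0("decoding_", lab),
                                       rho = gt$rho, p = gt$p, mode = gt$mode)
  }
  battery_means <- vapply(batteries, function(b) mean(b$table$mean_acc),
                          numeric(1))
  gt_mean <- gradient_order_test(battery_means, orders)
  gradient_rows[["battery_mean"]] <- data.frame(
    statistic = "decoding_battery_mean", rho = gt_mean$rho, p = gt_mean$p,
    mode = gt_mean$mode)
  gt_dist <- gradient_order_test(
    lapply(batteries, function(b)
      unlist(lapply(b$results, `[[`, "accuracies"))), orders)
  gradient_rows[["battery_dist"]] <- data.frame(
    statistic = "decoding_battery_distribution", rho = gt_dist$rho,
    p = gt_dist$p, mode = gt_dist$mode)

  decim <- NULL
  if (isTRUE(dec$run_decimation)) {
    decim_b <- lapply(datasets, decoder_battery, epochs = epochs,
                      n_pseudotrials = dec$n_pseudotrials,
                      n_reps = dec$n_reps, seed = seed, shuffle = FALSE,
                      decimate_to = dec$decimate_to)
    decim <- do.call(rbind, lapply(decim_b, `[[`, "table"))
    rownames(decim) <- NULL
    dm <- vapply(decim_b, function(b) mean(b$table$mean_acc), numeric(1))
    gd <- gradient_order_test(dm, orders)
    gradient_rows[["battery_mean_decimated"]] <- data.frame(
      statistic = "decoding_battery_mean_decimated", rho = gd$rho, p = gd$p,
      mode = gd$mode)
  }
  multinomial <- NULL
  if (isTRUE(dec$run_multinomial)) {
    mn <- dec$multinomial
    multinomial <- do.call(rbind, lapply(datasets, function(d) {
      r1 <- epoch_rates(bin_spikes(d$spikes, epochs$epoch1, d$trials))
      res <- multinomial_ev_decoder(r1, d$trials$ev1, n_bins = mn$n_bins,
                                    binning = mn$binning,
                                    n_pseudotrials = mn$n_pseudotrials,
                                    n_reps = mn$n_reps,
                                    seed = substream_seed(seed,
                                      paste0("mnl-", d$area)))
      data.frame(area = d$area, order_index = d$order_index,
                 overall = res$overall, n_bins = res$n_bins)
    }))
  }

  # --- intrinsic-property controls ----------------------------------------
  control_rows <- list()
  base <- vapply(datasets, function(d)
    baseline_rates(d$spikes, d$trials)$mean_rate, numeric(1))
  control_rows[["baseline"]] <- data.frame(
    area = areas, order_index = orders, metric = "baseline_rate",
    epoch = "pretrial", value = base, sem = NA_real_)
  for (epn in c("epoch1", "epoch2")) {
    ffs <- lapply(datasets, function(d)
      fano_factor(d$spikes, d$trials, epochs[[epn]]))
    control_rows[[paste0("ff_", epn)]] <- data.frame(
      area = areas, order_index = orders, metric = "fano_factor",
      epoch = epn, value = vapply(ffs, `[[`, numeric(1), "mean_ff"),
      sem = vapply(ffs, `[[`, numeric(1), "sem"))
    pcs <- lapply(datasets, function(d)
      pca_dimensionality(d$spikes, d$trials, epochs[[epn]]))
    for (sl in c("slope_12", "slope_23"))
      control_rows[[paste0(sl, "_", epn)]] <- data.frame(
        area = areas, order_index = orders, metric = paste0("pca_", sl),
        epoch = epn, value = vapply(pcs, `[[`, numeric(1), sl),
        sem = NA_real_)
  }
  controls <- do.call(rbind, control_rows); rownames(controls) <- NULL
  for (m in unique(paste(controls$metric, controls$epoch))) {
    sub <- controls[paste(controls$metric, controls$epoch) == m, ]
    gt <- tryCatch(gradient_order_test(sub$value, sub$order_index),
                   error = function(e) NULL)
    if (!is.null(gt))
      gradient_rows[[paste0("control_", m)]] <- data.frame(
        statistic = paste0("control_", gsub(" ", "_", m)), rho = gt$rho,
        p = gt$p, mode = gt$mode)
  }
  gradient_tests <- do.call(rbind, gradient_rows)
  rownames(gradient_tests) <- NULL

  report <- structure(list(
    config_hash = config_hash(config), seed = seed,
    areas = data.frame(area = areas, order_index = orders),
    behavior = behavior, tuning = tuning, latency_means = lat_means,
    latency_anova = lat_anova[c("F_area", "p_area", "F_offer", "p_offer")],
    signatures = signatures, acf = acf_tab, timescale_fits = fits,
    tau_gradient = tau_gradient, decoding = decoding,
    decoding_decimated = decim, multinomial = multinomial,
    controls = controls, gradient_tests = gradient_tests,
    failures = failures,
    provenance = list(
      tie_rule = "mean-split ties assigned to the low class",
      latency_convention = "bin centers, ties to earliest bin",
      excluded_acf_neurons = vapply(ts, function(t)
        attr(t$acf, "n_excluded"), numeric(1)),
      package_version = as.character(utils::packageVersion("mpfcgradient")))
  ), class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a run report to disk
#'
#' Emits `report.json` plus per-stage CSVs (`tuning.csv`, `latency.csv`,
#' `signatures.csv`, `acf.csv`, `timescale_fits.json`, `decoding.csv`,
#' `gradient_tests.csv`, `controls.csv`, `behavior.csv`).
#'
#' @param report A `"run_report"` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  wcsv <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  wcsv(report$tuning, "tuning.csv")
  wcsv(report$latency_means, "latency.csv")
  wcsv(report$signatures, "signatures.csv")
  wcsv(report$acf, "acf.csv")
  wcsv(report$decoding, "decoding.csv")
  wcsv(report$decoding_decimated, "decoding_decimated.csv")
  wcsv(report$gradient_tests, "gradient_tests.csv")
  wcsv(report$controls, "controls.csv")
  wcsv(data.frame(session = seq_along(report$behavior$proportions),
                  prop_higher_ev = report$behavior$proportions),
       "behavior.csv")
  jsonlite::write_json(report$timescale_fits,
                       file.path(out_dir, "timescale_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$behavior[c("t_test", "logistic")],
                       file.path(out_dir, "behavior_fit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  slim <- report
  slim$acf <- NULL  # bulky; kept in acf.csv
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", force = TRUE)
  invisible(out_dir)
}

#' Read back a written report
#'
#' @param out_dir Directory written by [write_report()].
#' @return The parsed `report.json` as a list.
#' @export
read_report <- function(out_dir) {
  p <- file.path(out_dir, "report.json")
  if (!file.exists(p)) stop("no report.json under ", out_dir)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

#' Write a simulated dataset the way the simulate interface does
#'
#' One `trials_<area>.csv`, `spikes_<area>.csv`, and
#' `ground_truth_<area>.json` per area.
#'
#' @param datasets From [generate_gradient_dataset()].
#' @param out_dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(datasets, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (d in datasets) {
    write_trials(d$trials, file.path(out_dir, paste0("trials_", d$area, ".csv")))
    write_spikes(d$spikes, file.path(out_dir, paste0("spikes_", d$area, ".csv")),
                 session_id = d$order_index)
    if (!is.null(d$neurons))
      jsonlite::write_json(d$neurons,
                           file.path(out_dir,
                                     paste0("ground_truth_", d$area, ".json")),
                           auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
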