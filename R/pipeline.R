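# End-to-end orchestration: model-prediction reports and the full analysis
# chain (filter -> epoch/downsample -> DSS -> spectrum -> tests) on
# synthetic datasets, behind a plain-list configuration that can be read
# from and written to YAML.

#' Default run configuration
#'
#' All defaults mirror the experiment and analysis as stated: 0.3-2.7 Hz
#' FIR band with a 10 s Hamming window, 6 retained DSS components, 2 s
#' onset removal, target frequencies 0.5/1/2 Hz, 100,000 bootstrap
#' resamples, 16 participants.
#'
#' @param seed Mandatory RNG seed for the whole run.
#' @param source_model Generating model for the synthetic data.
#' @param snr_db In-band SNR of the synthetic data (dB).
#' @param n_participants Number of synthetic participants.
#' @param per_sensor_phase Run the per-sensor bootstrap phase tests
#'   (slower; default `FALSE`).
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(seed, source_model = "rule_based_chunking",
                       snr_db = 10, n_participants = 16,
                       per_sensor_phase = FALSE) {
  structure(list(
    seed = seed,
    synthetic = synthetic_config(n_participants = n_participants,
                                 source_model = source_model,
                                 snr_db = snr_db, seed = seed),
    filter = list(band = c(0.3, 2.7), window_duration = 10),
    analysis = list(target_rate = 20, onset_removal = 2, n_dss = 6,
                    target_frequencies = c(0.5, 1, 2), f_chunk = 1,
                    n_resamples = 1e5, per_sensor_phase = per_sensor_phase,
                    per_sensor_resamples = 1e4)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config must set a seed")
  cfg <- run_config(seed = raw$seed)
  for (nm in intersect(names(raw$synthetic), names(cfg$synthetic)))
    cfg$synthetic[[nm]] <- raw$synthetic[[nm]]
  cfg$synthetic <- do.call(synthetic_config,
                           cfg$synthetic[names(formals(synthetic_config))])
  for (nm in intersect(names(raw$filter), names(cfg$filter)))
    cfg$filter[[nm]] <- raw$filter[[nm]]
  for (nm in intersect(names(raw$analysis), names(cfg$analysis)))
    cfg$analysis[[nm]] <- raw$analysis[[nm]]
  cfg
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Model-prediction report
#'
#' Simulates all three response models for both order types and summarizes
#' the predictions: which target frequencies carry spectral peaks and the
#' inter-condition phase difference at the chunk rate (1 Hz). The lexical
#' property model has no 1 Hz energy, so its phase difference is reported
#' as undefined (`NA`).
#'
#' @param config A [run_config()] (only the seed and sequence count are
#'   used).
#' @param n_sequences Sequences per cell for the averages (default 30).
#' @return A list of class `run_report` with `$predictions`, a data.frame
#'   of one row per model x order type.
#' @export
run_predictions <- function(config = run_config(seed = 1),
                            n_sequences = 30) {
  set.seed(config$seed)
  rows <- list()
  for (model in MODELS) for (ot in ORDER_TYPES) {
    ps <- predict_spectrum(model, "same_category", ot, n_sequences)
    pd <- predict_spectrum(model, "different_category", ot, n_sequences)
    power <- (ps$power + pd$power) / 2
    peaks <- find_spectral_peaks(power, ps$frequencies)
    near <- function(f) any(abs(peaks - f) < 1e-6)
    ph <- predict_phase_difference(model, ot, n_sequences)
    rows[[length(rows) + 1]] <- data.frame(
      model = model, order_type = ot,
      peak_0.5 = near(0.5), peak_1 = near(1), peak_2 = near(2),
      phase_difference = ph$phase_difference,
      phase_undefined = ph$undefined,
      stringsAsFactors = FALSE)
  }
  structure(list(predictions = do.call(rbind, rows),
                 seed = config$seed, n_sequences = n_sequences),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in intersect(c("predictions", "spectral", "power_difference"),
                       names(x))) {
    cat("$", nm, "\n", sep = "")
    print(x[[nm]])
  }
  if (!is.null(x$phase)) {
    cat("$phase\n")
    for (nm in names(x$phase)) {
      g <- x$phase[[nm]]$grand
      cat(sprintf(
        "  %s: mean diff %.1f deg, closer to %d deg, p = %.3g, 99%% CI (%.1f, %.1f)\n",
        nm, g$mean, g$closer_to, g$p, x$phase[[nm]]$ci[1],
        x$phase[[nm]]$ci[2]))
    }
  }
  invisible(x)
}

# preprocess one participant and return per-cell spectra (compensated),
# position-paired power and per-sensor phase
analyze_participant <- function(config, p, vocabulary, layout, filt) {
  rec <- generate_participant(config$synthetic, p, vocabulary)
  an <- config$analysis
  trials <- NULL; labels <- NULL
  for (cond in CONDITIONS) {
    b <- rec$blocks[[cond]]
    filtered <- apply_fir(b$data, filt)
    tr <- epoch_and_downsample(filtered, b$events$onset_s,
                               b$sampling_rate, an$target_rate)
    trials <- if (is.null(trials)) tr else
      array(c(trials, tr), c(dim(tr)[1:2], dim(trials)[3] + dim(tr)[3]))
    labels <- rbind(labels, b$events)
  }
  normal <- !labels$is_outlier
  trials <- trials[, , normal, drop = FALSE]
  labels <- labels[normal, , drop = FALSE]
  cells <- interaction(labels$condition, labels$order_type, drop = TRUE)
  dss <- dss_denoise(trials, cells, n_retained = an$n_dss)
  out <- list()
  for (cond in CONDITIONS) for (ot in ORDER_TYPES) {
    sel <- labels$condition == cond & labels$order_type == ot
    spec <- trial_spectrum(dss$denoised[, , sel, drop = FALSE],
                           sampling_rate = an$target_rate,
                           onset_removal = an$onset_removal)
    spec <- compensate_spectrum(spec, filt)
    paired <- pair_gradiometers(spec, layout)
    out[[paste(cond, ot, sep = ".")]] <- list(
      spectrum = spec,
      mean_power = colMeans(paired$power),
      frequencies = spec$frequencies)
  }
  out
}

#' Run the full analysis chain on a synthetic dataset
#'
#' For each participant (streamed, one at a time): generate the two
#' condition blocks, bandpass filter (0.3-2.7 Hz linear-phase FIR with
#' delay compensation), epoch to 12-s trials downsampled to 20 Hz, discard
#' outlier trials, apply a common DSS across condition cells retaining 6
#' components, average trials per cell, remove the first 2 s, DFT, and
#' compensate the filter's magnitude response. Across participants:
#' power-ratio peak tests at 0.5/1/2 Hz (F(2N,4N), FDR over the three
#' targets), between-order-type 1 Hz power comparisons (F(2N,2N)), and the
#' circular phase-difference analysis at 1 Hz with the participant
#' bootstrap test of 0 vs 180 degrees and its 99% shortest-arc CI.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `spectral` (data.frame of peak tests),
#'   `power_difference` (data.frame), `phase` (per order type: per-sensor
#'   angles, grand bootstrap, CI, optional per-sensor tests), `config`,
#'   `timings`.
#' @export
run_full_analysis <- function(config) {
  t0 <- Sys.time()
  an <- config$analysis
  vocabulary <- build_vocabulary()
  layout <- sensor_layout(config$synthetic$n_positions)
  filt <- fir_bandpass(config$filter$band,
                       config$synthetic$sampling_rate,
                       config$filter$window_duration)
  parts <- lapply(seq_len(config$synthetic$n_participants),
                  function(p) analyze_participant(config, p, vocabulary,
                                                  layout, filt))
  freqs <- parts[[1]][[1]]$frequencies
  cells <- names(parts[[1]])
  power <- lapply(cells, function(cl)
    do.call(rbind, lapply(parts, function(pt) pt[[cl]]$mean_power)))
  names(power) <- cells
  # spectral peak tests per cell, FDR across the three target frequencies
  spectral <- do.call(rbind, lapply(cells, function(cl) {
    tests <- lapply(an$target_frequencies, function(f)
      power_ratio_test(power[[cl]], freqs, f))
    data.frame(cell = cl,
               frequency = an$target_frequencies,
               PR = vapply(tests, `[[`, numeric(1), "PR"),
               df1 = vapply(tests, function(t) t$df[1], numeric(1)),
               df2 = vapply(tests, function(t) t$df[2], numeric(1)),
               p = vapply(tests, `[[`, numeric(1), "p"),
               stringsAsFactors = FALSE)
  }))
  spectral$q <- as.vector(vapply(cells, function(cl)
    fdr_correct(spectral$p[spectral$cell == cl]),
    numeric(length(an$target_frequencies))))
  # 1 Hz power: alternating vs random within condition
  power_difference <- do.call(rbind, lapply(CONDITIONS, function(cond) {
    tst <- power_difference_test(power[[paste(cond, "alternating",
                                              sep = ".")]],
                                 power[[paste(cond, "random", sep = ".")]],
                                 freqs, an$f_chunk)
    data.frame(condition = cond, f_target = an$f_chunk,
               ratio = tst$ratio, df1 = tst$df[1], df2 = tst$df[2],
               p = tst$p, stringsAsFactors = FALSE)
  }))
  # phase difference same - different at the chunk rate, per order type
  phase <- list()
  for (ot in ORDER_TYPES) {
    ang <- vapply(parts, function(pt)
      condition_phase_difference(pt[[paste("same_category", ot,
                                           sep = ".")]]$spectrum,
                                 pt[[paste("different_category", ot,
                                           sep = ".")]]$spectrum,
                                 an$f_chunk),
      numeric(nrow(layout)))       # sensors x participants
    per_participant <- apply(ang, 2, function(a)
      as.numeric(circular_mean(a)))
    grand <- bootstrap_closer_test(per_participant, an$n_resamples)
    entry <- list(sensor_angles = ang,
                  participant_means = per_participant,
                  grand = grand,
                  ci = phase_ci(grand$resamples, 0.99))
    if (isTRUE(an$per_sensor_phase))
      entry$per_sensor <- per_sensor_closer_test(ang,
                                                 an$per_sensor_resamples)
    phase[[ot]] <- entry
  }
  structure(list(spectral = spectral, power_difference = power_difference,
                 phase = phase, frequencies = freqs, power = power,
                 config = config,
                 timings = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))),
            class = "run_report")
}

#' Export a run report's tables to CSV/JSON
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$predictions))
    utils::write.csv(report$predictions,
                     file.path(dir, "predictions.csv"), row.names = FALSE)
  if (!is.null(report$spectral))
    utils::write.csv(report$spectral, file.path(dir, "spectral_tests.csv"),
                     row.names = FALSE)
  if (!is.null(report$power_difference))
    utils::write.csv(report$power_difference,
                     file.path(dir, "power_difference.csv"),
                     row.names = FALSE)
  if (!is.null(report$phase)) {
    summ <- lapply(report$phase, function(ph) list(
      mean_difference_deg = ph$grand$mean,
      closer_to = ph$grand$closer_to, p = ph$grand$p,
      ci99 = as.numeric(ph$ci)))
    jsonlite::write_json(summ, file.path(dir, "phase_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Write a trial dataset to an HDF5 container
#'
#' Layout: `/participants/p<i>/trials` (sensors x time x trials),
#' `/participants/p<i>/labels` (table), `/ground_truth` (JSON-serialized
#' config). Requires the `rhdf5` package.
#'
#' @param dataset A [generate_dataset()] result.
#' @param path Output `.h5` file.
#' @return `path`, invisibly.
#' @export
write_trial_dataset <- function(dataset, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("rhdf5 is required for HDF5 export")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "participants")
  for (i in seq_along(dataset$participants)) {
    g <- sprintf("participants/p%d", i)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(dataset$participants[[i]]$trials, path,
                   paste0(g, "/trials"))
    rhdf5::h5write(dataset$participants[[i]]$labels, path,
                   paste0(g, "/labels"))
  }
  rhdf5::h5write(
    as.character(jsonlite::toJSON(unclass_deep(dataset$config),
                                  auto_unbox = TRUE, digits = NA)),
    path, "ground_truth")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a trial dataset from an HDF5 container
#'
#' @param path An `.h5` file written by [write_trial_dataset()].
#' @return A `trial_dataset`.
#' @export
read_trial_dataset <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("rhdf5 is required for HDF5 import")
  idx <- rhdf5::h5ls(path)
  pgroups <- idx$name[idx$group == "/participants" & idx$otype == "H5I_GROUP"]
  pgroups <- pgroups[order(as.integer(sub("^p", "", pgroups)))]
  parts <- lapply(pgroups, function(g) list(
    trials = rhdf5::h5read(path, sprintf("participants/%s/trials", g)),
    labels = rhdf5::h5read(path, sprintf("participants/%s/labels", g))))
  cfg_json <- rhdf5::h5read(path, "ground_truth")
  cfg <- jsonlite::fromJSON(cfg_json)
  rhdf5::h5closeAll()
  structure(list(participants = parts,
                 layout = sensor_layout(cfg$n_positions), config = cfg),
            class = "trial_dataset")
}
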