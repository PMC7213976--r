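# Synthetic multi-sensor trial data with known ground truth: per-trial
# source waveforms from the configured response model, mixed into a
# 306-sensor array through smooth random topographies, embedded in 1/f
# background noise at a configured in-band SNR.

#' Sensor layout of the 306-sensor array
#'
#' 102 positions, each with one magnetometer and two collocated planar
#' gradiometers (306 sensors). Rows are ordered position-major
#' (mag, grad1, grad2 per position).
#'
#' @param n_positions Number of positions (default 102).
#' @return A data.frame with `sensor` (index), `position` (label),
#'   `sensor_type` (`"mag"`, `"grad1"`, `"grad2"`).
#' @export
sensor_layout <- function(n_positions = 102) {
  data.frame(
    sensor = seq_len(3 * n_positions),
    position = rep(sprintf("pos%03d", seq_len(n_positions)), each = 3),
    sensor_type = rep(c("mag", "grad1", "grad2"), n_positions),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic dataset generator
#'
#' Defaults state the emulated experiment: 16 participants, 306 sensors,
#' 12-s trials at a 2 Hz word rate sampled at 20 Hz, 30 sequences per
#' order type and condition of which 8 are outliers (so 22 analyzable
#' normal trials per cell), pink (1/f) background noise, and a +10 dB
#' in-band signal-to-noise ratio.
#'
#' @param n_participants Participants (default 16).
#' @param n_positions Sensor positions (default 102; 306 sensors).
#' @param sequences_per_order Sequences per order type per condition
#'   (default 30).
#' @param outliers_per_order Outlier sequences per order type (default 8;
#'   22 normal trials per cell remain).
#' @param source_model Generating model of the chunk-locked source, one of
#'   `"lexical_property"`, `"semantic_relatedness"`,
#'   `"rule_based_chunking"`.
#' @param snr_db Ratio (dB) of evoked-signal power to in-band
#'   (0.3-2.7 Hz) noise power, averaged over sensors. `-Inf` gives pure
#'   noise.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha noise
#'   (default 1).
#' @param word_rate_gain Amplitude of the 2 Hz word-rate component
#'   relative to the model waveform (default 1).
#' @param onset_gain Amplitude of the kernel-shaped onset transient
#'   (default 2; removed downstream by the 2-s onset discard).
#' @param phase_jitter_sd Per-trial latency jitter SD in seconds
#'   (default 0).
#' @param sampling_rate Generation rate in Hz (default 20, the analysis
#'   grid; any integer multiple of 20 exercises real downsampling).
#' @param iti_range Inter-sequence silent interval range in seconds
#'   (default `c(1, 2)`, uniform).
#' @param seed Mandatory RNG seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 16, n_positions = 102,
                             sequences_per_order = 30,
                             outliers_per_order = 8,
                             source_model = "rule_based_chunking",
                             snr_db = 10, noise_exponent = 1,
                             word_rate_gain = 1, onset_gain = 2,
                             phase_jitter_sd = 0,
                             sampling_rate = 20, iti_range = c(1, 2),
                             seed = 1) {
  source_model <- match.arg(source_model, MODELS)
  stopifnot(n_participants >= 1, sequences_per_order > outliers_per_order,
            outliers_per_order >= 0, is.finite(noise_exponent),
            noise_exponent >= 0, word_rate_gain >= 0, onset_gain >= 0,
            phase_jitter_sd >= 0, sampling_rate >= 20,
            sampling_rate %% 20 == 0)
  if (!is.finite(snr_db) && snr_db > 0) stop("snr_db may be -Inf, not +Inf")
  structure(as.list(environment()), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d participants, %d sensors, model %s, SNR %g dB, seed %d\n",
    x$n_participants, 3 * x$n_positions, x$source_model, x$snr_db, x$seed))
  invisible(x)
}

#' Gaussian noise with a 1/f^alpha power spectrum
#'
#' Spectral shaping: white Gaussian noise is transformed to the frequency
#' domain, scaled by f^(-alpha/2) (DC set to zero), and transformed back.
#' The output is standardized to unit variance and scaled by `scale`.
#'
#' @param n Samples per series.
#' @param alpha Spectral exponent (0 = white noise).
#' @param n_series Number of independent series (default 1).
#' @param scale Standard deviation of the output (default 1).
#' @return A vector (or `n_series x n` matrix) of noise.
#' @export
pink_noise <- function(n, alpha = 1, n_series = 1, scale = 1) {
  # generate on an FFT-friendly grid and truncate (stationary, so harmless)
  m <- stats::nextn(n, 2)
  shape <- pink_shape(m, alpha)
  w <- matrix(stats::rnorm(n_series * m), m, n_series)
  X <- stats::mvfft(w) * shape
  y <- Re(stats::mvfft(X, inverse = TRUE))[seq_len(n), , drop = FALSE] / m
  y <- sweep(y, 2, apply(y, 2, stats::sd), "/") * scale
  if (n_series == 1) drop(y) else t(y)
}

# amplitude shaping profile over DFT bins (two-sided), zero at DC
pink_shape <- function(n, alpha) {
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) / n           # two-sided frequency in cycles/sample
  shape <- c(0, f[-1]^(-alpha / 2))
  shape
}

# fraction of noise variance inside a band, from the shaping profile
pink_band_fraction <- function(n, alpha, band, sampling_rate) {
  shape2 <- pink_shape(n, alpha)^2
  f_hz <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)) / n) * sampling_rate
  sum(shape2[f_hz >= band[1] & f_hz <= band[2]]) / sum(shape2)
}

# smooth random sensor topography for one participant: a random combination
# of a shared low-rank spatial basis; gradiometers share the magnetometer
# pattern up to positive scale factors
participant_mixing <- function(basis, n_positions) {
  pattern <- drop(basis %*% stats::rnorm(ncol(basis)))
  pattern <- pattern / sqrt(mean(pattern^2))
  scales <- c(1, stats::runif(2, 0.5, 1.5))
  as.vector(rbind(pattern * scales[1], pattern * scales[2],
                  pattern * scales[3]))
}

# source waveform for one sequence: model response + word-rate train +
# onset transient, all on the generation grid
source_waveform <- function(sequence, config, kernel) {
  w <- convolve_pulses(model_pulses(sequence, config$source_model), kernel)
  s <- w$samples
  if (config$word_rate_gain > 0) {
    word_train <- new_pulse_train(sequence$onsets, rep(1, N_WORDS))
    s <- s + config$word_rate_gain *
      convolve_pulses(word_train, kernel)$samples
  }
  if (config$onset_gain > 0) {
    nk <- length(kernel$samples)
    s[seq_len(nk)] <- s[seq_len(nk)] + config$onset_gain * kernel$samples
  }
  s
}

# deterministic per-participant seeds derived from the config seed
participant_seeds <- function(config) {
  withr_seed <- config$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  sample.int(2^31 - 2, config$n_participants + 1)
}

#' Generate one participant's continuous recordings
#'
#' Builds both condition blocks for one participant: 60 sequences per
#' block (outliers included), a continuous sensor array with the evoked
#' signal mixed through the participant's topography, 1/f^alpha noise
#' scaled to the configured in-band SNR, and the event table. Fully
#' deterministic given the config seed and participant index.
#'
#' @param config A [synthetic_config()].
#' @param participant Participant index (1-based).
#' @param vocabulary Optional prebuilt vocabulary.
#' @return A list of class `participant_recording` with one element per
#'   condition: `data` (sensors x samples), `events` (data.frame with
#'   `onset_s`, `condition`, `order_type`, `is_outlier`), `mixing`
#'   (sensor vector), `sampling_rate`.
#' @export
generate_participant <- function(config, participant,
                                 vocabulary = build_vocabulary()) {
  seeds <- participant_seeds(config)
  set.seed(seeds[participant])
  fs <- config$sampling_rate
  kernel <- response_kernel(sampling_rate = fs)
  basis <- matrix(stats::rnorm(config$n_positions * 5), config$n_positions)
  mixing <- participant_mixing(basis, config$n_positions)
  n_sensors <- 3 * config$n_positions
  blocks <- lapply(CONDITIONS, function(cond) {
    block <- build_condition_block(cond, vocabulary,
                                   n_per_order = config$sequences_per_order,
                                   n_outliers_per_order =
                                     config$outliers_per_order)
    n_seq <- length(block$sequences)
    itis <- stats::runif(n_seq, config$iti_range[1], config$iti_range[2])
    onsets <- cumsum(c(itis[1], rep(SEQ_DURATION, n_seq - 1) +
                         itis[-1]))
    total_n <- ceiling((max(onsets) + SEQ_DURATION + 1) * fs)
    sig <- numeric(total_n)
    n_trial <- round(SEQ_DURATION * fs)
    jitter <- if (config$phase_jitter_sd > 0)
      stats::rnorm(n_seq, 0, config$phase_jitter_sd) else numeric(n_seq)
    for (j in seq_len(n_seq)) {
      s <- source_waveform(block$sequences[[j]], config, kernel)
      start <- round((onsets[j] + jitter[j]) * fs) + 1
      sig[start:(start + n_trial - 1)] <-
        sig[start:(start + n_trial - 1)] + s
    }
    data <- outer(mixing, sig)
    sig_var <- stats::var(sig[sig != 0]) * mean(mixing^2)
    if (is.finite(config$snr_db)) {
      q <- pink_band_fraction(stats::nextn(total_n, 2),
                              config$noise_exponent, c(0.3, 2.7), fs)
      noise_sd <- sqrt(sig_var / (q * 10^(config$snr_db / 10)))
      data <- data + pink_noise(total_n, config$noise_exponent,
                                n_series = n_sensors, scale = noise_sd)
    } else if (config$snr_db == -Inf) {
      # pure-noise dataset: unit-variance noise, no signal
      data <- pink_noise(total_n, config$noise_exponent,
                         n_series = n_sensors, scale = 1)
    }
    events <- data.frame(
      onset_s = onsets,
      condition = cond,
      order_type = vapply(block$sequences, `[[`, character(1),
                          "order_type"),
      is_outlier = vapply(block$sequences, `[[`, logical(1), "is_outlier"),
      stringsAsFactors = FALSE
    )
    list(data = data, events = events, sampling_rate = fs)
  })
  names(blocks) <- CONDITIONS
  structure(list(blocks = blocks, mixing = mixing,
                 participant = participant, config = config),
            class = "participant_recording")
}

#' Generate a full synthetic trial dataset
#'
#' Materializes every participant's epoched trials (no filtering or
#' denoising; see [run_full_analysis()] for the full chain). Intended for
#' small configurations; large runs should stream participants through
#' [generate_participant()].
#'
#' @param config A [synthetic_config()].
#' @return A list of class `trial_dataset`: `participants` (list; each has
#'   `trials` array sensors x time x trials at 20 Hz and a `labels`
#'   data.frame), `layout`, `config`.
#' @export
generate_dataset <- function(config) {
  layout <- sensor_layout(config$n_positions)
  parts <- lapply(seq_len(config$n_participants), function(p) {
    rec <- generate_participant(config, p)
    trials <- NULL; labels <- NULL
    for (cond in CONDITIONS) {
      b <- rec$blocks[[cond]]
      tr <- epoch_and_downsample(b$data, b$events$onset_s,
                                 b$sampling_rate, 20)
      trials <- if (is.null(trials)) tr else
        array(c(trials, tr), c(dim(tr)[1], dim(tr)[2],
                               dim(trials)[3] + dim(tr)[3]))
      labels <- rbind(labels, b$events)
    }
    list(trials = trials, labels = labels, mixing = rec$mixing)
  })
  structure(list(participants = parts, layout = layout, config = config),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- dim(x$participants[[1]]$trials)
  cat(sprintf(
    "<trial_dataset> %d participants, %d sensors, %d trials x %d samples each\n",
    length(x$participants), d[1], d[3], d[2]))
  invisible(x)
}
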