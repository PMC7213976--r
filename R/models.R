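# Three competing models of the evoked response to chunked word sequences.
# Each model reduces to a pulse train on the word-onset grid, convolved with
# a smooth response kernel.

MODELS <- c("lexical_property", "semantic_relatedness", "rule_based_chunking")

new_pulse_train <- function(times, amplitudes, sequence = NULL) {
  stopifnot(length(times) == length(amplitudes),
            all(is.finite(amplitudes)), all(amplitudes >= 0))
  structure(list(times = times, amplitudes = amplitudes, sequence = sequence),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses, amplitudes in [%g, %g]\n",
              length(x$times), min(x$amplitudes), max(x$amplitudes)))
  invisible(x)
}

#' Pulse train of the lexical property model
#'
#' One neural population tuned to a binary lexical feature (living or
#' nonliving things): a pulse is placed at every word onset with amplitude 1
#' when the word carries the feature and 0 otherwise. The living- and
#' nonliving-tuned populations are anti-correlated and sum to an all-ones
#' train.
#'
#' @param sequence A [stim_sequence] with categories assigned.
#' @param feature `"living"` or `"nonliving"`.
#' @return A `pulse_train`.
#' @export
lexical_pulses <- function(sequence, feature = c("living", "nonliving")) {
  feature <- match.arg(feature)
  target <- if (feature == "living") "L" else "N"
  new_pulse_train(sequence$onsets,
                  as.numeric(sequence$categories == target), sequence)
}

#' Binary lexical feature vectors of a sequence
#'
#' Two idealized features (living, nonliving); exactly one is 1 per word.
#'
#' @param sequence A [stim_sequence].
#' @return A 2 x 24 matrix with rows `living`, `nonliving`.
#' @export
lexical_features <- function(sequence) {
  rbind(living = as.numeric(sequence$categories == "L"),
        nonliving = as.numeric(sequence$categories == "N"))
}

#' Pulse train of the semantic relatedness model
#'
#' Neural adaptation/priming account: the response to each word is scaled by
#' one minus the Pearson correlation between its lexical feature vector and
#' that of the preceding word. In the two-feature idealization the
#' correlation is +1 for same-category neighbours and -1 for
#' different-category neighbours, so amplitudes are 0 and 2 respectively.
#' The first word has no predecessor; its amplitude defaults to the neutral
#' midpoint 1 (the first 2 s are discarded in all spectral analyses, so this
#' choice does not enter any statistic).
#'
#' @param sequence A [stim_sequence] with categories assigned.
#' @param first_amplitude Amplitude of the first word (default 1).
#' @return A `pulse_train`.
#' @export
relatedness_pulses <- function(sequence, first_amplitude = 1) {
  feats <- lexical_features(sequence)
  r <- vapply(2:ncol(feats),
              function(i) stats::cor(feats[, i], feats[, i - 1]), numeric(1))
  # r is exactly +/-1 in the two-feature idealization; strip fp noise
  amp <- round(1 - r, 9)
  new_pulse_train(sequence$onsets, c(first_amplitude, amp), sequence)
}

#' Pulse train of the rule-based chunking model
#'
#' Unit-amplitude pulses time-locked to chunk onsets (0, 1, ..., 11 s),
#' independent of word content, condition and order type.
#'
#' @param sequence A [stim_sequence].
#' @return A `pulse_train` with 12 unit pulses at integer seconds.
#' @export
chunk_pulses <- function(sequence) {
  new_pulse_train(sequence$onsets[seq(1, N_WORDS, by = CHUNK_LEN)],
                  rep(1, N_CHUNKS), sequence)
}

#' Gaussian response kernel
#'
#' The evoked response to a single pulse: a Gaussian window of 0.5 s
#' duration (compact support), peak at the window centre, unit peak
#' amplitude, with `sigma = duration/6` by default (the conventional
#' Gaussian-window parameterization). Model predictions are robust to the
#' exact shape; the invariant tests verify the phase predictions under
#' alternative widths.
#'
#' @param sampling_rate Samples per second (default 20, the analysis grid).
#' @param duration Kernel support in seconds (default 0.5).
#' @param sigma Gaussian standard deviation in seconds (default duration/6).
#' @return A `response_kernel`: list with `samples`, `sampling_rate`,
#'   `duration`.
#' @export
response_kernel <- function(sampling_rate = 20, duration = 0.5,
                            sigma = duration / 6) {
  t <- seq(0, duration, by = 1 / sampling_rate)
  structure(list(samples = exp(-0.5 * ((t - duration / 2) / sigma)^2),
                 sampling_rate = sampling_rate, duration = duration),
            class = "response_kernel")
}

#' Convolve a pulse train with a response kernel
#'
#' Linear convolution of the impulse series with the kernel, sampled on the
#' kernel's time grid; the tail beyond the sequence duration is truncated.
#'
#' @param pulses A `pulse_train`.
#' @param kernel A [response_kernel()].
#' @param duration Output duration in seconds (default 12).
#' @return A `sim_waveform`: list with `samples`, `sampling_rate`.
#' @export
convolve_pulses <- function(pulses, kernel, duration = SEQ_DURATION) {
  fs <- kernel$sampling_rate
  n <- round(duration * fs)
  idx <- round(pulses$times * fs) + 1
  if (any(abs(pulses$times * fs - (idx - 1)) > 1e-8))
    stop("pulse times do not fall on the kernel sampling grid")
  x <- numeric(n + length(kernel$samples))
  for (j in seq_along(idx))
    if (pulses$amplitudes[j] != 0) {
      ks <- idx[j]:(idx[j] + length(kernel$samples) - 1)
      x[ks] <- x[ks] + pulses$amplitudes[j] * kernel$samples
    }
  structure(list(samples = x[seq_len(n)], sampling_rate = fs),
            class = "sim_waveform")
}

model_pulses <- function(sequence, model) {
  switch(model,
         lexical_property = lexical_pulses(sequence, "living"),
         semantic_relatedness = relatedness_pulses(sequence),
         rule_based_chunking = chunk_pulses(sequence),
         stop("unknown model: ", model))
}

#' Simulate the response waveform of one model to one sequence
#'
#' @param sequence A [stim_sequence] with categories assigned.
#' @param model One of `"lexical_property"`, `"semantic_relatedness"`,
#'   `"rule_based_chunking"`.
#' @param kernel A [response_kernel()].
#' @return A `sim_waveform`.
#' @export
simulate_response <- function(sequence, model = MODELS,
                              kernel = response_kernel()) {
  model <- match.arg(model)
  w <- convolve_pulses(model_pulses(sequence, model), kernel)
  w$model <- model
  w$condition <- sequence$condition
  w$order_type <- sequence$order_type
  w
}

prediction_sequences <- function(condition, order_type, n_sequences) {
  if (order_type == "alternating")
    replicate(n_sequences, alternating_pattern(condition), simplify = FALSE)
  else
    replicate(n_sequences, random_pattern(condition), simplify = FALSE)
}

model_spectra <- function(model, condition, order_type, n_sequences, kernel) {
  seqs <- prediction_sequences(condition, order_type, n_sequences)
  vapply(seqs, function(s) {
    w <- simulate_response(s, model, kernel)
    dft_coefficients(waveform_segment(w))
  }, complex(trial_spectrum_len(kernel$sampling_rate)))
}

waveform_segment <- function(w, onset_removal = 2) {
  drop_n <- round(onset_removal * w$sampling_rate)
  w$samples[-seq_len(drop_n)]
}

trial_spectrum_len <- function(fs, duration = SEQ_DURATION,
                               onset_removal = 2) {
  round((duration - onset_removal) * fs)
}

#' Predicted average power spectrum of a model
#'
#' Simulates `n_sequences` sequences per the stated design, computes each
#' waveform's DFT after removing the first 2 s, and averages the power
#' across sequences (averaging power, not complex coefficients, matches a
#' spectrum averaged over sequences).
#'
#' @inheritParams simulate_response
#' @param condition,order_type Design cell to simulate.
#' @param n_sequences Sequences to average (default 30, the experiment's
#'   count per cell).
#' @return A list with `frequencies` (Hz) and `power`.
#' @export
predict_spectrum <- function(model = MODELS, condition = CONDITIONS,
                             order_type = ORDER_TYPES, n_sequences = 30,
                             kernel = response_kernel()) {
  model <- match.arg(model); condition <- match.arg(condition)
  order_type <- match.arg(order_type)
  X <- model_spectra(model, condition, order_type, n_sequences, kernel)
  n <- nrow(X)
  freqs <- (seq_len(n) - 1) / n * kernel$sampling_rate
  keep <- freqs <= kernel$sampling_rate / 2
  list(frequencies = freqs[keep], power = rowMeans(Mod(X)^2)[keep])
}

#' Find spectral peaks
#'
#' A bin is a peak when its power strictly exceeds both neighbouring bins
#' and exceeds `floor_frac` times the maximum power (guarding against
#' numerically-zero ripple). DC and the last bin are excluded.
#'
#' @param power Numeric vector of per-bin power.
#' @param frequencies Matching frequency vector (Hz).
#' @param floor_frac Relative power floor (default 1e-6).
#' @return Frequencies (Hz) of the peak bins.
#' @export
find_spectral_peaks <- function(power, frequencies, floor_frac = 1e-6) {
  n <- length(power)
  i <- 2:(n - 1)
  pk <- power[i] > power[i - 1] & power[i] > power[i + 1] &
    power[i] > floor_frac * max(power)
  frequencies[i][pk]
}

#' Predicted inter-condition phase difference of a model
#'
#' Simulates both conditions, averages the complex DFT coefficients at the
#' target frequency across sequences within each condition, and returns the
#' wrapped circular difference (same-category minus different-category).
#' When either condition's average coefficient is numerically zero (the
#' lexical property model at 1 Hz), the phase is undefined and `NA` is
#' returned with `undefined = TRUE`.
#'
#' @inheritParams predict_spectrum
#' @param f_target Target frequency in Hz (default 1, the chunk rate).
#' @return A list with `phase_difference` (degrees, wrapped to (-180, 180]),
#'   `undefined` flag, and the per-condition mean coefficients.
#' @export
predict_phase_difference <- function(model = MODELS,
                                     order_type = ORDER_TYPES,
                                     n_sequences = 30,
                                     f_target = 1,
                                     kernel = response_kernel()) {
  model <- match.arg(model); order_type <- match.arg(order_type)
  Xs <- model_spectra(model, "same_category", order_type, n_sequences, kernel)
  Xd <- model_spectra(model, "different_category", order_type, n_sequences,
                      kernel)
  n <- nrow(Xs)
  k <- freq_bin(f_target, kernel$sampling_rate, n)
  ms <- mean(Xs[k, ]); md <- mean(Xd[k, ])
  tol <- 1e-9 * sqrt(mean(Mod(Xs)^2) + mean(Mod(Xd)^2))
  if (Mod(ms) <= tol || Mod(md) <= tol)
    return(list(phase_difference = NA_real_, undefined = TRUE,
                same = ms, different = md))
  list(phase_difference = wrap_angle((Arg(ms) - Arg(md)) * 180 / pi),
       undefined = FALSE, same = ms, different = md)
}

freq_bin <- function(f, fs, n) {
  k <- f / fs * n
  if (abs(k - round(k)) > 1e-8) stop("frequency not on the DFT grid: ", f)
  round(k) + 1L
}
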