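# Frequency-domain analysis: trial-average DFT spectra, the power-ratio
# F-test against neighbouring bins, between-condition power F-tests, and
# FDR correction.

#' DFT coefficients of a real time series
#'
#' Plain DFT (no smoothing window), normalized by the series length so that
#' a unit-amplitude cosine at an on-grid frequency yields |X| = 0.5 at that
#' bin. Frequency resolution is 1/duration.
#'
#' @param x Numeric vector (or a matrix with one series per row).
#' @return Complex vector (or matrix) of the same length as `x`.
#' @export
dft_coefficients <- function(x) {
  if (is.matrix(x)) t(stats::mvfft(t(x))) / ncol(x)
  else stats::fft(x) / length(x)
}

#' Trial-averaged spectrum of sensor-array data
#'
#' Averages trials first, removes the first `onset_removal` seconds (to
#' avoid the response to sound onset), and applies the DFT per sensor. With
#' 12-s trials at 20 Hz and 2 s removed, the resolution is 0.1 Hz.
#'
#' @param trials Array `sensors x time x trials` (or a `sensors x time`
#'   matrix of an already-averaged response, or a plain vector for a single
#'   sensor).
#' @param sampling_rate Samples per second (default 20).
#' @param onset_removal Seconds removed from the start (default 2).
#' @return A `spectrum_result`: list with `coefficients` (complex,
#'   sensors x frequency), `frequencies` (Hz, DC to Nyquist),
#'   `sampling_rate`, `resolution`.
#' @export
trial_spectrum <- function(trials, sampling_rate = 20, onset_removal = 2) {
  if (is.vector(trials)) trials <- matrix(trials, nrow = 1)
  avg <- if (length(dim(trials)) == 3) {
    if (dim(trials)[3] < 1) stop("no trials")
    rowMeans(trials, dims = 2)
  } else trials
  drop_n <- round(onset_removal * sampling_rate)
  if (drop_n >= ncol(avg)) stop("trials shorter than the onset-removal span")
  seg <- avg[, -seq_len(drop_n), drop = FALSE]
  X <- dft_coefficients(seg)
  n <- ncol(seg)
  freqs <- (seq_len(n) - 1) / n * sampling_rate
  keep <- freqs <= sampling_rate / 2 + 1e-12
  structure(list(coefficients = X[, keep, drop = FALSE],
                 frequencies = freqs[keep],
                 sampling_rate = sampling_rate,
                 resolution = sampling_rate / n),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> %d sensors, %d bins (0-%.1f Hz, df = %.3g Hz)\n",
              nrow(x$coefficients), length(x$frequencies),
              max(x$frequencies), x$resolution))
  invisible(x)
}

spectrum_bin <- function(spectrum, f) {
  k <- which(abs(spectrum$frequencies - f) < spectrum$resolution / 100)
  if (length(k) != 1) stop("frequency not on the spectrum grid: ", f)
  k
}

#' Combine collocated sensors at each position
#'
#' Power: arithmetic mean of the two planar gradiometers per position.
#' Phase: circular mean over the collocated magnetometer + gradiometer
#' triplet.
#'
#' @param spectrum A [trial_spectrum()] result over the full 306-sensor
#'   array (rows ordered as in [sensor_layout()]).
#' @param layout A [sensor_layout()] data.frame.
#' @return A list with `power` (positions x frequency, gradiometer-pair
#'   mean) and `phase` (positions x frequency, degrees, triplet circular
#'   mean).
#' @export
pair_gradiometers <- function(spectrum, layout = sensor_layout()) {
  if (nrow(spectrum$coefficients) != nrow(layout))
    stop("spectrum sensor count does not match the layout")
  pow <- Mod(spectrum$coefficients)^2
  ph <- exp(1i * Arg(spectrum$coefficients))
  grad <- layout$sensor_type != "mag"
  lev <- unique(layout$position)
  pos_g <- factor(layout$position[grad], levels = lev)
  pos_a <- factor(layout$position, levels = lev)
  power <- rowsum(pow[grad, , drop = FALSE], pos_g) / 2
  zsum <- rowsum(Re(ph), pos_a) + 1i * rowsum(Im(ph), pos_a)
  phase <- Arg(zsum / 3) * 180 / pi
  list(power = power, phase = phase)
}

#' Power-ratio F-test for a spectral peak
#'
#' Tests whether the power at a target frequency exceeds the power in the
#' two neighbouring bins (one on each side), pooled over N participants:
#' `PR(fT) = 2 sum_k |Xk(fT)|^2 / sum_k (|Xk(fT-df)|^2 + |Xk(fT+df)|^2)`.
#' Under the null of equal power, PR follows F(2N, 4N); the p-value is the
#' upper tail. The degrees of freedom are kept at 2N/4N regardless of how
#' many sensors contributed to each participant's power (a conservative
#' choice when sensors are not fully correlated).
#'
#' @param power Matrix of response power, participants x frequency bins
#'   (e.g. gradiometer-pair power averaged over sensors per participant).
#' @param frequencies Frequency vector matching the columns (Hz).
#' @param f_target Target frequency (Hz); must not be the DC or edge bin.
#' @return A list of class `power_ratio_test`: `f_target`, `PR`, `df`,
#'   `p`, `n`.
#' @export
power_ratio_test <- function(power, frequencies, f_target) {
  power <- as.matrix(power)
  n_p <- nrow(power)
  if (n_p < 2) stop("need at least 2 participants")
  res <- diff(frequencies[1:2])
  k <- which(abs(frequencies - f_target) < res / 100)
  if (length(k) != 1) stop("target frequency not on the grid")
  if (k <= 1 || k >= length(frequencies))
    stop("target frequency has no neighbouring bin on both sides")
  pr <- 2 * sum(power[, k]) / sum(power[, k - 1] + power[, k + 1])
  df <- c(2 * n_p, 4 * n_p)
  structure(list(f_target = f_target, PR = pr, df = df,
                 p = stats::pf(pr, df[1], df[2], lower.tail = FALSE),
                 n = n_p),
            class = "power_ratio_test")
}

#' @export
print.power_ratio_test <- function(x, ...) {
  cat(sprintf("Power-ratio test at %.2g Hz: F(%d,%d) = %.3g, p = %.3g\n",
              x$f_target, x$df[1], x$df[2], x$PR, x$p))
  invisible(x)
}

#' Between-condition power F-test
#'
#' Compares the power at a target frequency between two conditions as the
#' ratio of participant-summed powers, two-sided under F(2N, 2N) — or
#' F(8N, 8N) when each condition's power is an average over the four
#' design cells (`pooled = TRUE`). Callers should only compare conditions
#' in which the target power is itself significant.
#'
#' @param power_a,power_b Matrices participants x frequency (same grid).
#' @param frequencies Frequency vector (Hz).
#' @param f_target Target frequency (Hz).
#' @param pooled Use the pooled F(8N, 8N) degrees of freedom.
#' @return A list of class `power_difference_test`: `f_target`, `ratio`,
#'   `df`, `p`.
#' @export
power_difference_test <- function(power_a, power_b, frequencies, f_target,
                                  pooled = FALSE) {
  power_a <- as.matrix(power_a); power_b <- as.matrix(power_b)
  stopifnot(nrow(power_a) == nrow(power_b))
  n_p <- nrow(power_a)
  res <- diff(frequencies[1:2])
  k <- which(abs(frequencies - f_target) < res / 100)
  if (length(k) != 1) stop("target frequency not on the grid")
  denom <- sum(power_b[, k])
  if (denom <= 0) stop("zero power in the denominator condition")
  ratio <- sum(power_a[, k]) / denom
  d <- if (pooled) 8 * n_p else 2 * n_p
  p_up <- stats::pf(ratio, d, d, lower.tail = FALSE)
  p <- min(1, 2 * min(p_up, 1 - p_up))
  structure(list(f_target = f_target, ratio = ratio, df = c(d, d), p = p),
            class = "power_difference_test")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (q-values); "FDR corrected" throughout the
#' analysis means this procedure.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
fdr_correct <- function(p) stats::p.adjust(p, method = "BH")
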