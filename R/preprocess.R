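# Sensor-space preprocessing: linear-phase FIR bandpass with spectral
# compensation, epoching/downsampling to the 20 Hz analysis grid, DSS
# denoising, and PCA waveform extraction.

#' Design a linear-phase FIR bandpass filter
#'
#' Windowed-sinc design: an ideal bandpass impulse response truncated to
#' `window_duration` seconds and tapered by a Hamming window. The result is
#' a symmetric (Type I, odd-length) filter, hence exactly linear phase with
#' a constant group delay of `(n_taps - 1) / 2` samples, and has the usual
#' windowed-sinc property of roughly -6 dB attenuation at the cut-off
#' frequencies.
#'
#' @param band Passband edges in Hz (default `c(0.3, 2.7)`).
#' @param sampling_rate Samples per second of the data to be filtered.
#' @param window_duration Window length in seconds (default 10).
#' @return A `fir_filter`: list with `coefficients`, `sampling_rate`,
#'   `band`, `group_delay` (samples).
#' @export
fir_bandpass <- function(band = c(0.3, 2.7), sampling_rate,
                         window_duration = 10) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] < sampling_rate / 2)
  n_taps <- round(window_duration * sampling_rate) + 1
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  m <- (n_taps - 1) / 2
  k <- seq_len(n_taps) - 1 - m
  sinc <- function(fc) {
    out <- 2 * fc / sampling_rate * rep(1, n_taps)
    nz <- k != 0
    out[nz] <- sin(2 * pi * fc / sampling_rate * k[nz]) / (pi * k[nz])
    out
  }
  h <- sinc(band[2]) - sinc(band[1])
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_taps) - 1) / (n_taps - 1))
  structure(list(coefficients = h * w, sampling_rate = sampling_rate,
                 band = band, group_delay = m),
            class = "fir_filter")
}

#' Complex frequency response of an FIR filter
#'
#' Evaluated directly from the coefficients at arbitrary frequencies; the
#' magnitude is what [compensate_spectrum()] divides out.
#'
#' @param filter A [fir_bandpass()] filter.
#' @param frequencies Frequencies in Hz.
#' @return Complex response vector.
#' @export
filter_response <- function(filter, frequencies) {
  n <- length(filter$coefficients)
  vapply(frequencies, function(f) {
    sum(filter$coefficients *
          exp(-1i * 2 * pi * f / filter$sampling_rate * (seq_len(n) - 1)))
  }, complex(1))
}

#' Apply a linear-phase FIR filter with delay compensation
#'
#' Forward FFT convolution followed by removal of the constant group delay,
#' yielding a zero-net-phase-shift output of the same length as the input
#' (edges zero-padded). This is what the downstream phase analyses require.
#'
#' @param x Numeric vector or matrix (one channel per row).
#' @param filter A [fir_bandpass()] filter.
#' @return Filtered data, same shape as `x`.
#' @export
apply_fir <- function(x, filter) {
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  h <- filter$coefficients
  if (n < length(h)) stop("data shorter than the filter")
  nfft <- stats::nextn(n + length(h) - 1, 2)
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  pad <- matrix(0, nfft, nrow(x))
  pad[seq_len(n), ] <- t(x)
  y <- stats::mvfft(stats::mvfft(pad) * H, inverse = TRUE)
  out <- t(Re(y[filter$group_delay + seq_len(n), , drop = FALSE]) / nfft)
  if (vec) drop(out) else out
}

#' Compensate a spectrum for the FIR filter's frequency response
#'
#' Each complex coefficient is divided by the filter's magnitude response
#' at its bin (the phase was already compensated by the constant-delay
#' correction in [apply_fir()]). Bins where the response is below `floor`
#' cannot be compensated and raise an error if requested.
#'
#' @param spectrum A [trial_spectrum()] result.
#' @param filter The [fir_bandpass()] filter that was applied.
#' @param floor Minimum magnitude response considered invertible
#'   (default 1e-3); bins below it are left untouched (they are outside
#'   the analysis band).
#' @return The compensated `spectrum_result`.
#' @export
compensate_spectrum <- function(spectrum, filter, floor = 1e-3) {
  g <- Mod(filter_response(filter, spectrum$frequencies))
  ok <- g >= floor
  spectrum$coefficients[, ok] <-
    sweep(spectrum$coefficients[, ok, drop = FALSE], 2, g[ok], "/")
  spectrum$compensated <- TRUE
  spectrum
}

#' Epoch continuous data and downsample to the analysis grid
#'
#' Cuts fixed-duration epochs at the event onsets and decimates to
#' `target_rate` by integer-factor subsampling (the bandpass filter is the
#' anti-alias filter: its upper edge is far below the target Nyquist).
#'
#' @param x Continuous data, channels x samples.
#' @param onsets Event onset times in seconds.
#' @param sampling_rate Input rate in Hz (must be an integer multiple of
#'   `target_rate`).
#' @param target_rate Output rate (default 20 Hz).
#' @param duration Epoch duration in seconds (default 12).
#' @return Array channels x time x trials at `target_rate`
#'   (`duration * target_rate` samples per trial).
#' @export
epoch_and_downsample <- function(x, onsets, sampling_rate, target_rate = 20,
                                 duration = SEQ_DURATION) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  fac <- sampling_rate / target_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop("sampling_rate must be an integer multiple of target_rate")
  fac <- round(fac)
  n_out <- round(duration * target_rate)
  out <- array(0, c(nrow(x), n_out, length(onsets)))
  for (j in seq_along(onsets)) {
    start <- round(onsets[j] * sampling_rate) + 1
    idx <- start + (seq_len(n_out) - 1) * fac
    if (start < 1 || max(idx) > ncol(x)) stop("epoch exceeds data bounds")
    out[, , j] <- x[, idx, drop = FALSE]
  }
  out
}

regularize <- function(C, load = 1e-9) {
  C + diag(load * sum(diag(C)) / nrow(C), nrow(C))
}

#' Denoising source separation (DSS) of trial data
#'
#' A linear decomposition that ranks components by the ratio of biased
#' (trial-averaged, i.e. stimulus-locked) variance to total variance. The
#' bias function is the response averaged over trials within each condition
#' cell; one common transform is derived from covariance matrices averaged
#' over cells. The first `n_retained` components are back-projected to the
#' sensor space.
#'
#' Implementation: the total covariance is computed from single trials and
#' shrunk by a small diagonal load, whitened by its eigendecomposition
#' (rank-truncated at `rank_tol` times the leading eigenvalue), and the
#' whitened bias covariance is eigendecomposed; this equals the generalized
#' eigendecomposition of (bias, total).
#'
#' @param trials Array channels x time x trials.
#' @param cells Factor (or vector) of length `n_trials` assigning each trial
#'   to a condition cell; a single cell if omitted.
#' @param n_retained Components kept for back-projection (default 6).
#' @param reg Diagonal loading fraction for the total covariance.
#' @param rank_tol Relative eigenvalue cutoff for whitening.
#' @return A list of class `dss_result`: `denoised` (same shape as
#'   `trials`), `unmixing` (components x channels), `mixing`
#'   (channels x components), `ratio` (bias/total variance per component),
#'   `n_retained`, `bias_cov`, `total_cov`.
#' @export
dss_denoise <- function(trials, cells = NULL, n_retained = 6,
                        reg = 1e-9, rank_tol = 1e-10) {
  d <- dim(trials)
  if (is.null(cells)) cells <- rep(1, d[3])
  cells <- as.factor(cells)
  if (min(table(cells)) < 2) stop("need at least 2 trials per cell")
  if (d[1] < n_retained) stop("fewer sensors than retained components")
  flat <- matrix(trials, d[1])
  c_total <- tcrossprod(flat) / ncol(flat)
  c_bias <- matrix(0, d[1], d[1])
  for (cl in levels(cells)) {
    avg <- rowMeans(trials[, , cells == cl, drop = FALSE], dims = 2)
    c_bias <- c_bias + tcrossprod(avg) / ncol(avg)
  }
  c_bias <- c_bias / nlevels(cells)
  c_total <- regularize(c_total, reg)
  e1 <- eigen(c_total, symmetric = TRUE)
  keep <- e1$values > rank_tol * e1$values[1]
  if (!any(keep)) stop("total covariance is singular")
  W <- diag(1 / sqrt(e1$values[keep]), sum(keep)) %*%
    t(e1$vectors[, keep, drop = FALSE])
  e2 <- eigen(W %*% c_bias %*% t(W), symmetric = TRUE)
  unmixing <- t(e2$vectors) %*% W
  # unmixing whitens c_total, so c_total %*% t(unmixing) is its right inverse
  mixing <- c_total %*% t(unmixing)
  sel <- seq_len(min(n_retained, nrow(unmixing)))
  proj <- mixing[, sel, drop = FALSE] %*% unmixing[sel, , drop = FALSE]
  den <- array(proj %*% flat, d)
  structure(list(denoised = den, unmixing = unmixing, mixing = mixing,
                 ratio = e2$values, n_retained = n_retained,
                 bias_cov = c_bias, total_cov = c_total),
            class = "dss_result")
}

#' @export
print.dss_result <- function(x, ...) {
  cat(sprintf("<dss_result> %d components, %d retained; top ratios: %s\n",
              length(x$ratio), x$n_retained,
              paste(signif(utils::head(x$ratio, 4), 3), collapse = ", ")))
  invisible(x)
}

#' PCA waveform extraction from trial-averaged sensor data
#'
#' Principal components of the sensor dimension of an averaged response
#' (conditions pooled by the caller). Component signs are normalized so the
#' sensor weight of largest magnitude is positive. Optionally the component
#' time courses are bandpass filtered around the chunk rate for display
#' (FIR, 2 s Hamming window, 0.75-1.25 Hz).
#'
#' @param avg Matrix sensors x time (trial-averaged response).
#' @param n_components Components to return (default 2).
#' @param band Optional display band in Hz, e.g. `c(0.75, 1.25)`; `NULL`
#'   for no filtering.
#' @param sampling_rate Needed when `band` is given (default 20).
#' @return A list: `timecourses` (components x time), `weights`
#'   (sensors x components), `variance_explained` (fractions).
#' @export
pca_waveform <- function(avg, n_components = 2, band = NULL,
                         sampling_rate = 20) {
  avg_c <- avg - rowMeans(avg)
  sv <- svd(avg_c, nu = n_components, nv = 0)
  w <- sv$u
  flip <- apply(w, 2, function(col) sign(col[which.max(abs(col))]))
  w <- sweep(w, 2, flip, "*")
  tc <- t(w) %*% avg_c
  if (!is.null(band)) {
    filt <- fir_bandpass(band, sampling_rate, window_duration = 2)
    tc <- apply_fir(tc, filt)
  }
  list(timecourses = tc, weights = w,
       variance_explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)])
}
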