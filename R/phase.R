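# Circular phase statistics: wrapped phase differences between conditions,
# the participant-resampling bootstrap test of 0 vs 180 degree phase
# locking, and shortest-arc confidence intervals. Angle arithmetic is done
# on unit vectors; degrees appear only at the interfaces.

#' Wrap angles to (-180, 180] degrees
#'
#' @param theta Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- theta %% 360
  ifelse(w > 180, w - 360, w)
}

#' Circular mean of a set of angles
#'
#' The argument of the (weighted) mean resultant vector. When the resultant
#' length is numerically zero the mean direction is undefined and `NA` is
#' returned with attribute `undefined = TRUE`.
#'
#' @param angles Angles in degrees.
#' @param weights Optional nonnegative weights.
#' @param tol Resultant-length threshold for the undefined flag.
#' @return Mean angle in degrees, wrapped to (-180, 180], with attributes
#'   `resultant` (mean resultant length) and `undefined`.
#' @export
circular_mean <- function(angles, weights = NULL, tol = 1e-9) {
  if (length(angles) == 0) stop("empty angle set")
  z <- exp(1i * angles * pi / 180)
  m <- if (is.null(weights)) mean(z) else
    sum(weights * z) / sum(weights)
  undef <- Mod(m) <= tol
  out <- if (undef) NA_real_ else wrap_angle(Arg(m) * 180 / pi)
  attr(out, "resultant") <- Mod(m)
  attr(out, "undefined") <- undef
  out
}

#' Per-sensor phase difference between two conditions
#'
#' The wrapped difference of DFT phases at a target frequency,
#' `angle(X_A) - angle(X_B)` per sensor. Sensors where either coefficient
#' is numerically zero get `NA`.
#'
#' @param spectrum_a,spectrum_b [trial_spectrum()] results on the same grid.
#' @param f_target Target frequency in Hz (default 1, the chunk rate).
#' @return Numeric vector of wrapped angles (degrees), one per sensor.
#' @export
condition_phase_difference <- function(spectrum_a, spectrum_b, f_target = 1) {
  k <- spectrum_bin(spectrum_a, f_target)
  xa <- spectrum_a$coefficients[, k]
  xb <- spectrum_b$coefficients[, k]
  scale <- sqrt(mean(Mod(spectrum_a$coefficients)^2) +
                mean(Mod(spectrum_b$coefficients)^2))
  d <- wrap_angle((Arg(xa) - Arg(xb)) * 180 / pi)
  d[Mod(xa) <= 1e-12 * scale | Mod(xb) <= 1e-12 * scale] <- NA_real_
  d
}

closer_to_zero <- function(theta) abs(wrap_angle(theta)) < 90

#' Bootstrap significance level from the closer-to-zero count
#'
#' The two-sided significance level when `A` of `n_resamples` bootstrap
#' resamples fall closer to 0 than to 180 degrees:
#' `2 * min(A + 1, n_resamples + 1 - A) / (n_resamples + 1)`, capped at 1.
#'
#' @param A Number of resamples closer to 0 degrees.
#' @param n_resamples Total resamples (default 100000).
#' @return The significance level.
#' @export
phase_test_p <- function(A, n_resamples = 1e5) {
  min(1, 2 * min(A + 1, n_resamples + 1 - A) / (n_resamples + 1))
}

#' Bootstrap test: is the mean phase difference closer to 0 or 180 degrees?
#'
#' Participants are resampled with replacement `n_resamples` times; each
#' resample's circular-mean phase difference is classified as closer to 0
#' than to 180 degrees iff its absolute wrapped value is below 90 degrees
#' (ties at exactly 90 count as not closer). If A resamples fall closer to
#' 0, the two-sided significance level is
#' `2 * min(A + 1, n_resamples + 1 - A) / (n_resamples + 1)`, capped at 1.
#'
#' @param angles Per-participant phase differences in degrees.
#' @param n_resamples Bootstrap resamples (default 100000).
#' @return A list of class `phase_bootstrap`: `p`, `A`, `closer_to` (0 or
#'   180), `mean` (observed circular mean, degrees), `resamples` (the
#'   resampled circular means, degrees), `n_resamples`.
#' @export
bootstrap_closer_test <- function(angles, n_resamples = 1e5) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 2) stop("need at least 2 participants")
  z <- exp(1i * angles * pi / 180)
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                nrow = n_resamples)
  zm <- matrix(z[idx], nrow = n_resamples)
  res <- wrap_angle(Arg(rowMeans(zm)) * 180 / pi)
  a <- sum(closer_to_zero(res))
  p <- phase_test_p(a, n_resamples)
  structure(list(p = p, A = a,
                 closer_to = if (a >= n_resamples / 2) 0 else 180,
                 mean = as.numeric(circular_mean(angles)),
                 resamples = res, n_resamples = n_resamples),
            class = "phase_bootstrap")
}

#' @export
print.phase_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Phase bootstrap: mean difference %.1f deg, closer to %d deg (A = %d/%d), p = %.3g\n",
    x$mean, x$closer_to, x$A, x$n_resamples, x$p))
  invisible(x)
}

#' Shortest-arc circular confidence interval
#'
#' The smallest angular arc covering `level` of the resampled phase
#' differences, reported as signed degree bounds.
#'
#' @param resamples Resampled angles in degrees (e.g. from
#'   [bootstrap_closer_test()]).
#' @param level Coverage (default 0.99).
#' @return Numeric `c(lower, upper)` in degrees, wrapped to (-180, 180];
#'   `lower > upper` indicates an arc crossing the 180-degree cut.
#' @export
phase_ci <- function(resamples, level = 0.99) {
  th <- sort(resamples %% 360)
  b <- length(th)
  m <- ceiling(level * b)
  if (m >= b) m <- b
  ext <- c(th, th + 360)
  widths <- ext[seq_len(b) + m - 1] - th
  j <- which.min(widths)
  lo <- th[j]
  hi <- ext[j + m - 1]
  out <- wrap_angle(c(lo, hi))
  names(out) <- c("lower", "upper")
  out
}

#' Per-sensor bootstrap phase tests with FDR correction
#'
#' Runs [bootstrap_closer_test()] independently per sensor (resampling
#' participants within sensor) and applies Benjamini-Hochberg correction
#' across sensors.
#'
#' @param angle_matrix Sensors x participants matrix of wrapped phase
#'   differences (degrees).
#' @param n_resamples Resamples per sensor.
#' @return A data.frame with one row per sensor: `sensor`, `mean_diff`,
#'   `closer_to`, `p`, `q`.
#' @export
per_sensor_closer_test <- function(angle_matrix, n_resamples = 1e4) {
  angle_matrix <- as.matrix(angle_matrix)
  res <- lapply(seq_len(nrow(angle_matrix)), function(s)
    bootstrap_closer_test(angle_matrix[s, ], n_resamples))
  out <- data.frame(
    sensor = seq_len(nrow(angle_matrix)),
    mean_diff = vapply(res, function(r) r$mean, numeric(1)),
    closer_to = vapply(res, function(r) r$closer_to, numeric(1)),
    p = vapply(res, function(r) r$p, numeric(1))
  )
  out$q <- fdr_correct(out$p)
  out
}
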