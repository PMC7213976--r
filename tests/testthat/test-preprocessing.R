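test_that("the FIR bandpass is linear phase with -6 dB cut-offs", {
  filt <- fir_bandpass(c(0.3, 2.7), sampling_rate = 20)
  h <- filt$coefficients
  expect_equal(h, rev(h))  # symmetric taps: exactly linear phase
  gain_db <- function(f) 20 * log10(Mod(filter_response(filt, f)))
  expect_equal(gain_db(0.3), -6, tolerance = 1)
  expect_equal(gain_db(2.7), -6, tolerance = 1)
  expect_equal(gain_db(1), 0, tolerance = 0.2)     # passband
  expect_lt(gain_db(0.05), -30)                    # stopband
  expect_lt(gain_db(5), -40)
})

test_that("filtering preserves in-band signals with zero net phase shift", {
  filt <- fir_bandpass(c(0.3, 2.7), 20)
  t <- seq(0, 60, by = 0.05)
  x <- sin(2 * pi * 1 * t)
  y <- apply_fir(x, filt)
  mid <- 301:900  # away from edge transients
  expect_equal(y[mid], x[mid], tolerance = 0.02)
  x_lo <- sin(2 * pi * 0.05 * t)
  expect_lt(max(abs(apply_fir(x_lo, filt)[mid])), 0.05)
  expect_error(apply_fir(rnorm(50), filt), "shorter")
})

test_that("spectrum compensation inverts the filter gain (round trip < 1%)", {
  filt <- fir_bandpass(c(0.3, 2.7), 20)
  t <- seq(0, 120, by = 0.05)
  x <- cos(2 * pi * 0.5 * t + 0.7)
  y <- apply_fir(x, filt)
  tr <- epoch_and_downsample(y, c(30, 50, 70), 20)
  sp <- compensate_spectrum(trial_spectrum(tr), filt)
  k <- which(sp$frequencies == 0.5)
  expect_equal(2 * Mod(sp$coefficients[1, k]), 1, tolerance = 0.01)
  # compensation changes power by the inverse squared magnitude response
  raw <- trial_spectrum(tr)
  g <- Mod(filter_response(filt, 0.5))
  expect_equal(Mod(sp$coefficients[1, k])^2,
               Mod(raw$coefficients[1, k])^2 / g^2)
})

test_that("epoching cuts 240-sample trials and preserves phase", {
  fs <- 100
  t <- seq(0, 100, by = 1 / fs)
  x <- cos(2 * pi * 1 * t)
  tr <- epoch_and_downsample(x, c(10, 30), fs, 20)
  expect_equal(dim(tr), c(1, 240, 2))
  sp <- trial_spectrum(tr)
  k <- which(sp$frequencies == 1)
  # epoch starts at t=10s: cos(2*pi*(t+10)) == cos(2*pi*t); after the 2 s
  # onset removal the segment starts at phase 0
  expect_equal(Arg(sp$coefficients[1, k]), 0, tolerance = 1e-6)
  expect_equal(dim(epoch_and_downsample(x, numeric(0), fs, 20))[3], 0)
  expect_error(epoch_and_downsample(x, 95, fs, 20), "bounds")
  expect_error(epoch_and_downsample(x, 10, fs, 30), "multiple")
})

test_that("DSS recovers a repeated waveform from noisy trials", {
  set.seed(70)
  n_sensors <- 12; n_time <- 240; n_trials <- 30
  wave <- sin(2 * pi * 1 * seq(0, 11.95, by = 0.05))
  mix <- rnorm(n_sensors)
  trials <- array(0, c(n_sensors, n_time, n_trials))
  for (j in 1:n_trials)
    trials[, , j] <- outer(mix, wave) +
      matrix(rnorm(n_sensors * n_time, sd = 2), n_sensors)
  dss <- dss_denoise(trials, n_retained = 1)
  comp1 <- drop(dss$unmixing[1, , drop = FALSE] %*%
                  rowMeans(trials, dims = 2))
  expect_gt(abs(cor(comp1, wave)), 0.95)
  # denoised average resembles the clean sensor signal
  den_avg <- rowMeans(dss$denoised, dims = 2)
  expect_gt(abs(cor(as.vector(den_avg), as.vector(outer(mix, wave)))), 0.9)
})

test_that("retaining all components reproduces the input", {
  set.seed(71)
  trials <- array(rnorm(6 * 50 * 8), c(6, 50, 8))
  dss <- dss_denoise(trials, n_retained = 6)
  expect_equal(dss$denoised, trials, tolerance = 1e-6)
})

test_that("DSS equals the generalized eigendecomposition (brute force)", {
  set.seed(72)
  trials <- array(rnorm(5 * 40 * 10), c(5, 40, 10))
  trials[2, , ] <- trials[2, , ] + sin(seq_len(40) / 3)
  dss <- dss_denoise(trials, n_retained = 2)
  # oracle: eigen of C_total^-1 C_bias (non-symmetric brute force)
  ev <- eigen(solve(dss$total_cov, dss$bias_cov))
  expect_equal(sort(dss$ratio, decreasing = TRUE),
               sort(Re(ev$values), decreasing = TRUE), tolerance = 1e-6)
  # leading generalized eigenvector matches component 1 up to sign/scale
  v_pkg <- dss$unmixing[1, ]
  v_ora <- Re(ev$vectors[, which.max(Re(ev$values))])
  # compare as directions in the C_total metric
  cosang <- abs(sum(v_pkg * (dss$total_cov %*% v_ora))) /
    sqrt(sum(v_pkg * (dss$total_cov %*% v_pkg)) *
         sum(v_ora * (dss$total_cov %*% v_ora)))
  expect_equal(cosang, 1, tolerance = 1e-6)
})

test_that("pure-noise DSS ratios cluster near the trial-averaging chance level", {
  set.seed(73)
  n_trials <- 25
  trials <- array(rnorm(8 * 100 * n_trials), c(8, 100, n_trials))
  dss <- dss_denoise(trials, n_retained = 2)
  # averaging n independent trials leaves ~1/n of the single-trial variance
  expect_lt(max(dss$ratio), 5 / n_trials)
  expect_gt(min(dss$ratio), 0)
})

test_that("DSS rejects degenerate inputs", {
  trials <- array(rnorm(4 * 30 * 6), c(4, 30, 6))
  expect_error(dss_denoise(trials, cells = rep(1:6, 1)), "2 trials")
  expect_error(dss_denoise(trials, n_retained = 10), "fewer sensors")
})

test_that("PCA separates constructed components and normalizes signs", {
  # rank-1 data
  tc <- sin(seq(0, 20, length.out = 200))
  rank1 <- outer(c(1, -2, 3), tc)
  p <- pca_waveform(rank1, n_components = 1)
  expect_gt(p$variance_explained[1], 0.999)
  expect_gt(p$weights[which.max(abs(p$weights[, 1])), 1], 0)
  # onset transient + 1 Hz oscillation with distinct topographies
  t <- seq(0, 11.95, by = 0.05)
  onset <- exp(-((t - 0.3) / 0.15)^2)
  osc <- sin(2 * pi * t)
  set.seed(74)
  a <- rnorm(10); b <- rnorm(10)
  b <- b - a * sum(a * b) / sum(a^2)  # orthogonal topographies
  data <- outer(a, onset) + outer(b, osc)
  p2 <- pca_waveform(data, n_components = 2)
  cors <- abs(cor(t(p2$timecourses), cbind(onset, osc)))
  expect_gt(max(cors[, 1]), 0.95)
  expect_gt(max(cors[, 2]), 0.95)
})

test_that("the preprocessing chain is linear", {
  set.seed(75)
  filt <- fir_bandpass(c(0.3, 2.7), 20)
  x1 <- matrix(rnorm(3 * 2000), 3)
  x2 <- matrix(rnorm(3 * 2000), 3)
  expect_equal(apply_fir(x1 + x2, filt),
               apply_fir(x1, filt) + apply_fir(x2, filt), tolerance = 1e-9)
  on <- c(10, 40)
  expect_equal(epoch_and_downsample(x1 + x2, on, 20, 20),
               epoch_and_downsample(x1, on, 20, 20) +
                 epoch_and_downsample(x2, on, 20, 20))
  # DSS back-projection with a fixed transform is linear by construction
  trials <- array(rnorm(5 * 60 * 6), c(5, 60, 6))
  dss <- dss_denoise(trials, n_retained = 2)
  proj <- dss$mixing[, 1:2] %*% dss$unmixing[1:2, ]
  flat <- matrix(trials, 5)
  expect_equal(array(proj %*% flat, dim(trials)), dss$denoised)
})
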