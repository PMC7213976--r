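test_that("lexical pulse amplitudes are the binary feature values", {
  s <- alternating_pattern("same_category")   # NNLL repeated
  liv <- lexical_pulses(s, "living")
  expect_equal(liv$amplitudes, rep(c(0, 0, 1, 1), 6))
  expect_equal(liv$times, s$onsets)
  nl <- lexical_pulses(s, "nonliving")
  expect_equal(liv$amplitudes + nl$amplitudes, rep(1, 24))
  all_n <- seq_from_categories(strrep("N", 24))
  expect_equal(lexical_pulses(all_n, "living")$amplitudes, rep(0, 24))
})

test_that("relatedness amplitudes equal 1 - cor of consecutive binary features", {
  # independent oracle: evaluate 1 - Pearson r for the two binary 2-vectors
  amp_oracle <- function(prev, cur)
    1 - cor(c(prev == "L", prev == "N"), c(cur == "L", cur == "N"))
  expect_equal(amp_oracle("L", "L"), 0)
  expect_equal(amp_oracle("L", "N"), 2)
  s <- alternating_pattern("same_category")
  r <- relatedness_pulses(s)
  expected <- c(1, vapply(2:24, function(i)
    amp_oracle(s$categories[i - 1], s$categories[i]), numeric(1)))
  expect_equal(r$amplitudes, expected)
  # NNLL...: amplitude-2 pulses at words 3, 5, 7, ... (chunk onsets)
  expect_equal(which(r$amplitudes == 2), seq(3, 23, by = 2))
  d <- relatedness_pulses(alternating_pattern("different_category"))
  # NLLN...: amplitude-2 pulses at even words (chunk-final, 0.5 s offset)
  expect_equal(which(d$amplitudes == 2), seq(2, 24, by = 2))
  const <- relatedness_pulses(seq_from_categories(strrep("L", 24)))
  expect_equal(const$amplitudes[-1], rep(0, 23))
})

test_that("chunk pulses are 12 unit pulses at integer seconds for any sequence", {
  set.seed(7)
  for (s in list(alternating_pattern("same_category"),
                 alternating_pattern("different_category"),
                 random_pattern("same_category"),
                 random_pattern("different_category"))) {
    p <- chunk_pulses(s)
    expect_equal(p$times, 0:11)
    expect_equal(p$amplitudes, rep(1, 12))
  }
})

test_that("convolution places kernel copies and is linear", {
  k <- response_kernel()
  one <- chunktag:::new_pulse_train(3, 1)
  w <- convolve_pulses(one, k)
  expect_length(w$samples, 240)
  idx <- 61:71
  expect_equal(w$samples[idx], k$samples)
  expect_true(all(w$samples[-idx] == 0))
  zero <- chunktag:::new_pulse_train(c(1, 2), c(0, 0))
  expect_equal(convolve_pulses(zero, k)$samples, rep(0, 240))
  # off-grid pulse times are an error
  bad <- chunktag:::new_pulse_train(0.33, 1)
  expect_error(convolve_pulses(bad, k), "grid")
})

test_that("the chunk-model waveform is 1 Hz periodic after the transient", {
  s <- alternating_pattern("same_category")
  w <- simulate_response(s, "rule_based_chunking")
  x <- w$samples[41:240]  # discard first 2 s
  expect_equal(x[21:200], x[1:180], tolerance = 1e-12)
})

test_that("a 0.5 s delay rotates the 1 Hz phase by exactly 180 degrees", {
  # DFT shift theorem oracle on the package's own analysis segment
  set.seed(4)
  x <- rnorm(200)
  shifted <- c(tail(x, 10), head(x, 190))  # circular 0.5 s shift at 20 Hz
  X <- brute_dft(x); Xs <- brute_dft(shifted)
  k1 <- 11  # 1 Hz at 0.1 Hz resolution
  d <- wrap_angle((Arg(Xs[k1]) - Arg(X[k1])) * 180 / pi)
  expect_equal(abs(d), 180, tolerance = 1e-8)
})

test_that("relatedness trains for the two conditions differ by a 0.5 s shift", {
  rs <- relatedness_pulses(alternating_pattern("same_category"))
  rd <- relatedness_pulses(alternating_pattern("different_category"))
  # within the analysis window (first 2 s removed) the amplitude-2 pulse
  # times differ by exactly +0.5 s; the trains differ only at the edges
  ts <- rs$times[rs$amplitudes == 2]
  td <- rd$times[rd$amplitudes == 2]
  expect_equal(td[td >= 2.5], ts[ts >= 2] + 0.5)
  cs <- chunk_pulses(alternating_pattern("same_category"))
  cd <- chunk_pulses(alternating_pattern("different_category"))
  expect_identical(cs$times, cd$times)
  expect_identical(cs$amplitudes, cd$amplitudes)
})

test_that("model responses depend only on categories, not the filled words", {
  v <- build_vocabulary()
  set.seed(12)
  pat <- random_pattern("different_category")
  filled <- fill_words(pat, v)
  for (m in c("lexical_property", "semantic_relatedness",
              "rule_based_chunking"))
    expect_equal(simulate_response(pat, m)$samples,
                 simulate_response(filled, m)$samples)
})

test_that("predicted spectra show the stated peaks per model", {
  set.seed(2)
  ps <- predict_spectrum("lexical_property", "same_category", "alternating")
  peaks <- find_spectral_peaks(ps$power, ps$frequencies)
  expect_true(0.5 %in% peaks)
  expect_false(1 %in% peaks)
  for (m in c("semantic_relatedness", "rule_based_chunking")) {
    pk <- find_spectral_peaks(predict_spectrum(m, "same_category",
                                               "alternating")$power,
                              ps$frequencies)
    expect_true(all(c(1, 2) %in% pk))
  }
  # rule-based prediction identical across conditions, random order
  pr1 <- predict_spectrum("rule_based_chunking", "same_category", "random",
                          n_sequences = 5)
  pr2 <- predict_spectrum("rule_based_chunking", "different_category",
                          "random", n_sequences = 5)
  expect_equal(pr1$power, pr2$power)
})

test_that("predicted 1 Hz phase differences match the three models", {
  expect_equal(predict_phase_difference("rule_based_chunking",
                                        "alternating")$phase_difference, 0)
  expect_equal(abs(predict_phase_difference("semantic_relatedness",
                                            "alternating")$phase_difference),
               180)
  lex <- predict_phase_difference("lexical_property", "alternating")
  expect_true(lex$undefined)
  expect_true(is.na(lex$phase_difference))
  set.seed(31)
  rnd <- predict_phase_difference("semantic_relatedness", "random",
                                  n_sequences = 30)
  expect_lt(abs(abs(rnd$phase_difference) - 180), 15)
})

test_that("phase predictions are robust to the kernel width", {
  for (sig in c(0.05, 0.125)) {
    k <- response_kernel(sigma = sig)
    expect_equal(predict_phase_difference("rule_based_chunking",
                                          "alternating",
                                          kernel = k)$phase_difference, 0)
    expect_equal(abs(predict_phase_difference("semantic_relatedness",
                                              "alternating",
                                              kernel = k)$phase_difference),
                 180)
  }
})
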