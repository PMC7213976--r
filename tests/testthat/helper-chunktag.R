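# Shared fixtures and independent oracles.

# brute-force O(n^2) DFT, normalized like dft_coefficients()
brute_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * k / n)) / n, complex(1))
}

# a stim_sequence with an arbitrary category string (test-only constructor)
seq_from_categories <- function(categories, condition = "same_category",
                                order_type = "alternating") {
  chunktag:::new_stim_sequence(strsplit(categories, "")[[1]],
                               condition, order_type)
}

# small synthetic config: 10 positions (30 sensors), 4 sequences per order
tiny_config <- function(seed, ...) {
  synthetic_config(n_participants = 3, n_positions = 10,
                   sequences_per_order = 4, outliers_per_order = 1,
                   seed = seed, ...)
}

tiny_run_config <- function(seed, ...) {
  cfg <- run_config(seed = seed, ...)
  cfg$synthetic <- tiny_config(seed,
                               source_model = cfg$synthetic$source_model,
                               snr_db = cfg$synthetic$snr_db)
  cfg$analysis$n_resamples <- 2000
  cfg
}
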