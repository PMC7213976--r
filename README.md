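# chunktag

Frequency tagging and circular phase analysis of chunk-rate neural
tracking in isochronous word sequences.

## The problem

Listeners can group a sequence of spoken words into multi-word *chunks*
using an explicitly learned rule. Low-frequency cortical activity shows
spectral peaks at the chunk presentation rate — but a peak alone does not
prove chunk-level representation: responses tuned to properties of the
individual words, or to the semantic relatedness of neighbouring words,
can also produce slow rhythms. `chunktag` is for researchers who want to
adjudicate between these accounts with frequency-tagged MEG/EEG-style
data, or to validate such an analysis chain end to end on synthetic data
with known ground truth.

The design: words from two semantic categories (living `L`, nonliving `N`)
are presented at 2 Hz; pairs of words form 1 s chunks; 12 chunks form a
12 s sequence. Two chunking rules (valid chunks `LL`/`NN` vs `NL`/`LN`)
and two orders (alternating `NNLL…`/`NLLN…` vs random) are contrasted.
Three models make distinct predictions at the 1 Hz chunk rate:

| model | 1 Hz peak | inter-condition 1 Hz phase difference |
|---|---|---|
| lexical property | none (peaks at 0.5 Hz + odd harmonics) | undefined |
| semantic relatedness | yes | 180° |
| rule-based chunking | yes | 0° |

The statistical core is the power-ratio F-test
`PR(f_T) = 2 Σ_k |X_k(f_T)|² / Σ_k (|X_k(f_T−Δf)|² + |X_k(f_T+Δf)|²)`
with `PR ~ F(2N, 4N)` under the null over `N` participants, plus a
participant-resampling bootstrap of whether the circular mean phase
difference is closer to 0° or 180°, with significance
`2·min(A+1, 100001−A)/100001` over 100,000 resamples and a 99%
shortest-arc confidence interval.

The package provides:

* the symbolic stimulus generator (conditions, order types, outlier
  sequences, condition blocks) — `build_vocabulary()`,
  `build_condition_block()`, …
* the three response models as pulse trains convolved with a Gaussian
  kernel — `lexical_pulses()`, `relatedness_pulses()`, `chunk_pulses()`,
  `predict_spectrum()`, `predict_phase_difference()`
* a synthetic multi-sensor MEG-like generator (306 sensors, 1/f noise,
  configurable SNR and source model) — `synthetic_config()`,
  `generate_dataset()`
* the preprocessing chain: linear-phase FIR bandpass with spectral
  compensation, epoching/downsampling, DSS denoising, PCA waveforms
* the statistics: `power_ratio_test()`, `power_difference_test()`,
  `fdr_correct()`, `circular_mean()`, `bootstrap_closer_test()`,
  `phase_ci()`
* orchestration: `run_predictions()`, `run_full_analysis()`, a YAML
  config, CSV/JSON/HDF5 export, and a CLI (`inst/cli/chunktag.R`).

## Worked example

```r
library(chunktag)
rep <- run_predictions(run_config(seed = 1))
rep$predictions
#>                  model  order_type peak_0.5 peak_1 peak_2 phase_difference phase_undefined
#> 1     lexical_property alternating     TRUE  FALSE   TRUE               NA            TRUE
#> 2     lexical_property      random    FALSE  FALSE   TRUE        -89.96506           FALSE
#> 3 semantic_relatedness alternating    FALSE   TRUE   TRUE        180.00000           FALSE
#> 4 semantic_relatedness      random    FALSE   TRUE   TRUE        180.00000           FALSE
#> 5  rule_based_chunking alternating    FALSE   TRUE   TRUE          0.00000           FALSE
#> 6  rule_based_chunking      random    FALSE   TRUE   TRUE          0.00000           FALSE
```

Reading the table: only the word-level lexical model produces the 0.5 Hz
(four-word unit) peak and lacks a 1 Hz chunk-rate peak; the other two
models both peak at 1 Hz but are separated by the inter-condition phase
difference — 180° for relatedness, 0° for chunking. (The lexical model's
1 Hz phase is undefined for alternating sequences because it has no 1 Hz
energy; for random order its phase difference is broadly distributed.)
The 2 Hz word-rate peak appears in every model.

Stimuli are symbolic and fully bookkept:

```r
set.seed(1)
v <- build_vocabulary()
block <- build_condition_block("same_category", v)
block
#> <condition_block> same_category: 60 sequences (16 outliers)
block$sequences[[1]]
#> <stim_sequence> same_category / alternating
#>   categories: NNLLNNLLNNLLNNLLNNLLNNLL
#>   words filled: 24
```

A full synthetic analysis (filter → epoch → DSS → spectrum → tests) runs
from one config; with a rule-based source at +10 dB SNR it detects the
1 Hz and 2 Hz peaks (FDR q < 0.05), leaves 0.5 Hz flat, and concludes the
phase difference is closer to 0°:

```r
report <- run_full_analysis(run_config(seed = 1))
report$spectral          # power-ratio tests per cell and frequency
report$phase$alternating$grand   # bootstrap phase test
```

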