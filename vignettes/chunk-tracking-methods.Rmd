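---
title: "Methods: frequency tagging and phase analysis of chunk-rate neural tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency tagging and phase analysis of chunk-rate neural tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chunktag)
```

## The scientific question

When listeners hear an isochronous sequence of spoken words and are asked to
group consecutive pairs of words into chunks according to an explicitly
learned rule, does low-frequency cortical activity track the chunks
themselves, or can apparent chunk-rate activity be explained by properties
of the individual words? `chunktag` implements the full simulation and
analysis machinery needed to pose and answer that question with
frequency-tagged M/EEG-style data.

The design presents disyllabic words at 2 Hz; two words form a 1 s chunk,
and 12 chunks form a 12 s sequence. Words come from two semantic categories,
living (L) and nonliving (N). Two chunking rules are contrasted: in the
*same-category* condition valid chunks are LL and NN; in the
*different-category* condition they are NL and LN. Sequences are either
*alternating-order* (the two valid chunks interleaved: the four-word unit
NNLL or NLLN repeated six times) or *random-order* (each chunk drawn i.i.d.
from the two valid chunks). Because the alternating-order sequences of the
two conditions differ only by a one-word (0.5 s) lag, the phase of any
1 Hz word-driven response must differ by 180° between conditions, whereas a
response locked to chunk boundaries keeps the same phase. That single
contrast — 0° versus 180° at the chunk rate — separates chunk-level from
word-level accounts.

## The three response models

All three models are pulse trains on the word-onset grid, convolved with a
smooth response kernel (`response_kernel()`: a Gaussian window of 0.5 s
compact support, unit peak, `sigma = duration/6`).

* **Lexical property** (`lexical_pulses()`): a neural population tuned to a
  binary word feature (living or nonliving); the pulse amplitude is the
  binary feature value. For alternating-order sequences the four-word
  periodicity produces spectral peaks at 0.5 Hz and its odd harmonics
  (plus the 2 Hz word rate) and *no* 1 Hz component.
* **Semantic relatedness** (`relatedness_pulses()`): an adaptation/priming
  account; each word's amplitude is one minus the Pearson correlation of
  its binary feature vector with the preceding word's (0 for same-category
  neighbours, 2 for different-category neighbours). This yields a 1 Hz
  peak whose phase differs by 180° between conditions.
* **Rule-based chunking** (`chunk_pulses()`): unit pulses at chunk onsets,
  independent of word content — a 1 Hz response with a 0° inter-condition
  phase difference.

Two modelling choices are not fixed by the design and are therefore
explicit parameters:

* **First-word relatedness amplitude.** The first word has no predecessor.
  We use the neutral midpoint 1 (`first_amplitude`), and note that the
  first 2 s of every trial are discarded before any spectral analysis, so
  the choice cannot enter any statistic.
* **Kernel shape.** Only the 0.5 s duration is constrained; the phase
  predictions are invariant to the width, which the test suite verifies for
  `sigma` ∈ {0.05, 0.125} s. The convolution tail beyond 12 s is truncated.

Predicted spectra (`predict_spectrum()`) average *power* across sequences;
a spectrum "averaged over all sequences" is a power average, and averaging
complex coefficients would cancel the random-order models' energy.
Predicted phase differences (`predict_phase_difference()`) average
*complex* coefficients within condition — the only average with a
well-defined mean phase. Both defaults use 30 sequences per cell, the
experiment's count. The lexical model has numerically zero 1 Hz energy for
alternating sequences, so its phase difference is flagged `undefined`
rather than silently returning noise.

## Synthetic data: the stated world

`synthetic_config()` encodes the emulated experiment, and its defaults are
the stated conditions, not tuning knobs: 16 participants; 102 sensor
positions each carrying one magnetometer and two collocated gradiometers
(306 sensors); per condition, 30 alternating- and 30 random-order sequences
of which 8 + 8 are outliers, leaving 22 analyzable normal trials per
condition × order-type cell; 12 s trials on a 20 Hz grid; 1/f background
noise; +10 dB in-band SNR.

Per trial, the sensor signal is `M · s(t) + noise`, where `s(t)` is the
configured model's waveform for that trial's sequence plus a 2 Hz word-rate
component (`word_rate_gain`, default 1 — every word evokes a response
regardless of model) and a kernel-shaped onset transient (`onset_gain`,
default 2, mimicking the dominant onset response; it is removed by the 2 s
onset discard). `M` is a per-participant smooth random topography (a random
combination of a low-rank spatial basis); the two gradiometers share the
magnetometer's pattern up to positive scale factors, which is all the
collocated-sensor analysis relies on. The noise is Gaussian with a
1/f^α spectrum (α = 1 by default); its amplitude is set analytically so
that the ratio of evoked-signal variance to noise variance *inside the
0.3–2.7 Hz analysis band*, averaged over sensors, equals `snr_db`.
`snr_db = -Inf` produces pure noise for null calibration. Sequences within
a block are separated by uniform 1–2 s silent intervals, and outlier trials
are generated and labelled so the pipeline can demonstrate excluding them.

What the generator does *not* emulate: spatially correlated sensor noise,
ocular/movement artifacts, head-position changes, between-participant
anatomy, or any acoustic variability. A green recovery test therefore
establishes that the analysis chain is correct and well-calibrated — not
that it would survive every pathology of real recordings.

The +10 dB default deserves a note: the paper does not report per-trial
SNR, so the value was chosen once to make the desk-scale experiment
decisive (the real effect, F ≈ 5–6 at 1 Hz over 16 participants, is far
weaker). It is a property of the synthetic world, not a claim about MEG.

## The analysis chain

`run_full_analysis()` executes the stages in the published order, streaming
one participant at a time to bound memory:

1. **Bandpass filter** (`fir_bandpass()`, `apply_fir()`): 0.3–2.7 Hz
   windowed-sinc FIR, 10 s Hamming window, odd tap count — exactly linear
   phase. The windowed-sinc design has its −6 dB points at the cut-offs,
   matching the stated attenuation. Filtering is forward FFT convolution
   followed by exact group-delay removal, so the net phase shift is zero —
   a precondition for every phase statistic downstream.
2. **Epoch and downsample** (`epoch_and_downsample()`): 12 s epochs at
   event onsets, integer-factor decimation to 20 Hz (the bandpass is the
   anti-alias filter). Outlier trials are dropped before statistics.
3. **DSS denoising** (`dss_denoise()`): components ranked by the ratio of
   trial-averaged ("biased") variance to total variance; bias covariances
   are computed per condition cell and averaged so one common transform
   serves all conditions; the first 6 components are back-projected.
   Numerics: the total covariance gets a diagonal load of 1e−9 × trace/n
   and whitening truncates eigenvalues below 1e−10 × the leading one.
   The implementation is the whitened symmetric eigendecomposition, which
   the tests verify against a brute-force generalized eigendecomposition.
4. **Spectrum** (`trial_spectrum()`, `compensate_spectrum()`): trials are
   averaged first, the first 2 s discarded (onset response), and the plain
   DFT applied per sensor — 0.1 Hz resolution over the remaining 10 s.
   Each coefficient is divided by the filter's magnitude response at its
   bin (phase was already delay-compensated; bins where the response is
   below 1e−3 are outside the band and left untouched).
5. **Statistics**: described next.

## Statistics

**Spectral peaks.** `power_ratio_test()` computes
`PR(fT) = 2 Σₖ|Xₖ(fT)|² / Σₖ(|Xₖ(fT−Δf)|² + |Xₖ(fT+Δf)|²)` over N
participants, F(2N, 4N)-distributed under the null of equal power. The
degrees of freedom are *not* inflated when power is averaged over sensors
(a deliberate, conservative choice). Targets are 0.5, 1 and 2 Hz, with
Benjamini–Hochberg FDR across the three frequencies; DC and the Nyquist
bin are excluded as targets. Between-condition comparisons
(`power_difference_test()`) use the two-sided ratio of participant-summed
powers under F(2N, 2N), or F(8N, 8N) for four-cell-pooled ROI-style
comparisons.

**Phase.** Per sensor and participant, the wrapped difference of 1 Hz
phases between conditions (`condition_phase_difference()`); participants'
sensor-wise circular means feed a bootstrap (`bootstrap_closer_test()`):
participants are resampled with replacement 100,000 times, each resample's
grand circular mean is classified as closer to 0° than 180° iff its
absolute wrapped value is below 90° (a tie at exactly 90° counts as
not-closer — the unique distance dichotomy on the circle), and the
two-sided significance level is `2·min(A+1, 100001−A)/100001`
(`phase_test_p()`). The 99% CI (`phase_ci()`) is the shortest arc covering
99% of the resampled means. Per-sensor maps repeat the test per sensor
with FDR across sensors (`per_sensor_closer_test()`). All angle arithmetic
is on unit vectors; degrees appear only at interfaces, wrapped to
(−180°, 180°]. A zero resultant or zero coefficient yields a flagged
`NA`, never an exception.

Two resolved ambiguities: the grand test resamples the *participant-level*
circular means over sensors (matching "phase difference averaged over all
sensors"), and the counting formula is used verbatim even though the text
names a BCa bootstrap — the text's own CI description is percentile-style,
and the formula is what is printed.

## Numerical and degenerate-input conventions

* PCA component signs are normalized so the largest-magnitude sensor
  weight is positive; DSS components inherit sign indeterminacy, and all
  tests compare up to sign/scale.
* Pulse times must fall on the kernel grid (error otherwise); pink noise is
  synthesized on an FFT-friendly padded grid and truncated (R's FFT is
  quadratic for prime lengths).
* `epoch_and_downsample()` errors on epochs outside the data span and on
  non-integer decimation factors; `trial_spectrum()` errors when the
  onset-removal span exceeds the trial.
* The power-ratio test refuses target bins without two neighbours.

## What the tests establish

The suite contains per-module unit tests, property-style invariants
(binomial chunk-draw calibration, DFT-vs-brute-force, DSS-vs-generalized
eigendecomposition, shift-theorem phase rotation, filter round-trip,
linearity of the preprocessing chain, SNR monotonicity of the power ratio,
null calibration on pure noise) and an acceptance suite that (1) checks
the three models' spectral/phase signatures, (2) checks the stimulus
bookkeeping, (3) calibrates the power-ratio statistic against F(32, 64)
over 10,000 null replicates and the bootstrap formula exactly, (4) runs
the full pipeline at the stated world for both chunk-driven and
relatedness-driven sources, requiring phase recovery within 10° and
correct peak detection at q < 0.05, and (5) verifies the oracle
equivalences. The synthetic scale in unit tests is reduced (fewer
positions/sequences) purely for runtime; the acceptance runs use the full
stated world.
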