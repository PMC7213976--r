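Package: chunktag
Title: Frequency Tagging and Circular Phase Analysis of Chunk-Rate Neural Tracking
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how low-frequency neural activity tracks
    multi-word chunks in isochronous spoken word sequences. The package
    generates chunk-structured symbolic stimuli (same-category and
    different-category chunking rules, alternating and random chunk order,
    outlier sequences), simulates three competing models of the evoked
    response (lexical property, semantic relatedness, rule-based chunking)
    as pulse trains convolved with a Gaussian response kernel, synthesises
    multi-sensor MEG-like trial data with known ground truth and 1/f
    background noise, and implements the full sensor-space analysis chain:
    linear-phase FIR bandpass filtering with spectral compensation,
    epoching and downsampling, denoising source separation (DSS), DFT
    spectra, the power-ratio F-test against neighbouring frequency bins,
    between-condition power F-tests, Benjamini-Hochberg FDR correction,
    and circular phase-difference statistics with a participant-level
    bootstrap test of 0 degree versus 180 degree phase locking and
    shortest-arc confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    optparse
Config/testthat/edition: 3
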