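Package: painlfp
Title: Event-Aligned LFP Spectral Analysis and Pain-Memory Behavioral Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for event-aligned spectral analysis of single-channel local
    field potential (LFP) recordings from nociceptive and aversive behavioral
    experiments: zero-phase Butterworth band-limiting to 2-45 Hz, Welch-style
    windowed power spectral density with Hanning taper and 50% overlap,
    decibel conversion and Gaussian smoothing along frequency, segmentation of
    trials into prestimulus/stimulus/poststimulus phases anchored on stimulus
    onset and paw withdrawal, and mean band power (delta, theta, alpha, beta,
    gamma) per trial, phase, and compartment. Includes behavioral scoring
    (paw-withdrawal thresholds from ramp readings, conditioned place aversion
    scores from compartment occupancy), one-way repeated-measures and mixed
    two-way ANOVA implemented from sums of squares with Bonferroni post hoc
    tests, a seeded synthetic-data generator emulating the control/model/
    treatment study design, and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
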