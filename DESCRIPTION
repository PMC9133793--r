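Package: oddwave
Title: Time-Resolved Multivariate Mismatch Decoding for Roving-Oddball MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the neural representation of a repeated
    ("standard") auditory stimulus emerges over repetitions in
    magnetoencephalography, using the roving-oddball paradigm. Generates
    psychometrically anchored stimulus sets and transition-balanced train
    designs, simulates sensor-level epochs with ground-truth deviance and
    repetition-attenuation components, applies artifact rejection, zero-phase
    low-pass filtering and baseline z-normalization, performs time-resolved
    pairwise decoding with multivariate noise normalization (shrinkage
    covariance), pseudo-trial averaging and cross-validation, computes
    temporal-generalization matrices, and provides cluster-corrected
    sign-permutation inference together with bootstrap onset/peak latency
    tests. A study orchestrator reproduces the structure of a two-group
    repetition-accrual analysis on synthetic cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
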