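Package: psaeegnet
Title: Pyramid Squeeze Attention Networks for Single-Trial P300 Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compact convolutional networks with pyramid squeeze attention
    (PSA) for single-trial classification of P300 event-related potentials
    in rapid serial visual presentation (RSVP) experiments. Provides the
    PSAEEGNet architecture and its ablation family (EEGNet control, single-
    and dual-attention variants, multi-scale kernel sweeps), a faithful
    training protocol for heavily class-imbalanced oddball data
    (class-weighted cross-entropy, plateau learning-rate halving, early
    stopping with best-weight restoration), stratified k-fold
    cross-validation drivers, the standard evaluation metrics (accuracy,
    TPR, FPR, F1, pairwise AUC), EEG preprocessing utilities (channel
    selection, zero-phase Butterworth band-pass, epoch extraction), and a
    seeded generator of synthetic RSVP recordings with 1/f plus alpha
    background noise and a parametric P300 template, so the full pipeline
    is testable without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
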