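Package: placeboeeg
Title: Placebo Response Prediction from Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline for predicting placebo response in
    depression trials from resting-state EEG. Provides a synthetic
    19-channel cohort generator with plantable spectral and demographic
    effects, rule-based artifact rejection and fixed-shape segmentation,
    stochastic training-time augmentation, a small eight-block
    one-dimensional convolutional network with two-stage fine-tuning
    (remission pre-training, placebo-arm fine-tuning with layer freezing),
    bootstrap ensemble evaluation, bootstrapped mixed-effects regression of
    predictions on per-channel band power, and Holm-corrected correlation
    screening against behavioural metadata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    lme4,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
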