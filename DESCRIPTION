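Package: eegdx
Title: Resting-State EEG Feature-Map CNN Pipeline for Depression Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for diagnosing depression and
    grading its severity from resting-state EEG. Provides a synthetic cohort
    generator (19-channel 10-20 EEG with 1/f background, alpha rhythm with a
    controllable frontal asymmetry effect, eye blinks, line noise and
    questionnaire scales tied to a latent severity), EDF input/output, an
    EEGLAB-style preprocessing chain (zero-phase FIR bandpass and notch
    filtering, 2 s epoching, bad-channel detection and spherical-spline
    interpolation, ICA blink removal, +/-70 uV amplitude rejection and a
    greater-than-50-percent effective-segment screening rule), time-domain
    feature-map imaging of 10 s windows, a small convolutional network trained
    by stochastic gradient descent producing an AI score in [0,1], 10-fold
    cross-validated diagnostic metrics with bootstrap AUC confidence
    intervals, and Spearman correlation of AI scores against clinical scales.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
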