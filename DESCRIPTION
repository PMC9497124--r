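Package: cogniscreen
Title: Multimodal EEG, Eye-Tracking and Neuropsychological Screening for
    Mild Cognitive Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for community-level screening of mild
    cognitive impairment (MCI) against normal controls from low-cost
    multimodal data: single-channel EEG, eye tracking, and a
    neuropsychological test battery. Provides EEG denoising and
    segmentation, spectral band powers via the autocorrelation
    (Wiener-Khinchin) spectrum, nonlinear regularity and complexity
    measures (approximate entropy, sample entropy, multiscale entropy,
    Lempel-Ziv complexity), I-VT oculomotor event detection and gaze
    metrics, minimum-redundancy-maximum-relevance (MRMR) feature
    ranking by mutual information, and support-vector-machine
    classification with stratified cross-validation, ROC/AUC with
    bootstrap confidence intervals, and a four-model multimodal
    comparison. A synthetic-cohort generator with configurable group
    effects makes every stage testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    e1071,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
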