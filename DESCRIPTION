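Package: facesync
Title: Facial-Behavior Coordination Features and Diagnosis Classification
Version: 0.1.0
Authors@R:
    person("Facesync", "Developers", email = "facesync-dev@example.org",
           role = c("aut", "cre"))
Description: Quantifies within-person coordination of facial behavior from
    per-frame 3D face-model fits and uses it to predict diagnostic group
    membership. A dense face mesh is partitioned into four regions by
    nearest landmark, a region-localized expression basis is built from a
    global PCA-style basis, and per-frame deformations are projected onto
    it. Expression coefficients and head-pose angles form a 56-channel
    behavior matrix from which windowed forward-lag maximal
    cross-correlation summaries (mean and standard deviation per ordered
    channel pair) are extracted. A linear maximum-margin classifier with
    nested cross-validation over the window length predicts diagnosis;
    further tools compare model predictions with panels of human raters and
    summarize classifier weights by facial-region category. A synthetic
    cohort generator (lag-coupled autoregressive channels, logistic rater
    panels) makes the whole pipeline testable without access to video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
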