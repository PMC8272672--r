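Package: kneefusion
Title: Multimodal Feature Fusion for Knee MRI Injury Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying a multimodal feature-fusion approach to
    knee MRI injury classification on synthetic phantoms. Provides a
    seeded phantom generator for sagittal, coronal and transverse
    knee-like slices with controllable anterior cruciate ligament and
    meniscus tear lesions; a frozen convolutional backbone with top-down
    feature-pyramid fusion; a batch-normalization, adaptive-max-pooling
    and projection head producing a deep feature vector alongside 32
    handcrafted image statistics; an energy-based (restricted Boltzmann
    machine) fusion classifier trained by contrastive divergence with a
    logistic output head; classification metrics including trapezoidal
    ROC/AUC; and grade-scale concordance and chi-square statistics for
    comparing an imaging modality against an arthroscopic reference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
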