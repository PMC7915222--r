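Package: patchboost
Title: Boosted EfficientNet Classification of Small Histopathology Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for binary classification of small (96x96) histopathology
    image patches such as the Patch Camelyon lymph-node-metastasis tiles,
    where the discriminative signal is confined to the central 32x32 region.
    Implements Random Center Cropping (a pad-then-crop augmentation that
    always preserves the central block), an EfficientNet-B3-topology
    convolutional backbone with optional reduced downsampling scale (stem
    stride 2 to 1), squeeze-and-excitation channel attention, and a
    multi-block feature-fusion classifier head, together with a seeded
    synthetic patch generator, evaluation metrics (accuracy, AUC,
    sensitivity, specificity, F-measure) and a training/ablation harness.
    All network forward and backward passes are implemented in the package
    (C++ convolution kernels, R layers) so the full pipeline runs on a CPU
    without external deep-learning frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
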