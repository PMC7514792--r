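Package: retiqa
Title: Retinal Image Quality Assessment with Global No-Reference Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic quality assessment of color fundus photographs.
    Locates the circular field of view and removes its hard border by
    iterative extension, extracts 40 global no-reference quality features
    (block spatial and spectral entropies, a trainable natural-scene
    statistics naturalness distance, Mexican-hat continuous-wavelet
    sharpness measures, and HSV-value luminosity percentiles), selects
    non-redundant features with a bootstrap-stabilised fast
    correlation-based filter, and classifies adequate versus inadequate
    quality with a SMOTE-balanced multilayer perceptron whose operating
    threshold is chosen on the training ROC curve. Includes a seeded
    synthetic fundus generator with controllable defocus and vignetting
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    png,
    jpeg,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
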