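Package: boxseg
Title: Weakly Supervised Image Segmentation from Bounding-Box Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains pixel-level segmentation models from bounding-box
    annotations by iterative pseudo-mask refinement. Provides the
    oval-ring confidence loss mask and masked binary cross-entropy,
    three pseudo-mask initializers (solid circle, clipped model
    prediction, and a hybrid of the two), a compact CPU encoder-decoder
    segmentation network with a desk-scale preset, mixed-supervision
    training that pools ground-truth masks with box-derived targets,
    dice/accuracy/confusion evaluation with k-fold cross-validation,
    a seeded synthetic polyp-scene generator so the whole pipeline is
    testable without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
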