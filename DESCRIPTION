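Package: noduleCNN
Title: Convolutional Neural Networks for Pulmonary Nodule False-Positive Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the false-positive-reduction stage of lung computer
    aided detection (CAD) pipelines on thoracic CT. Implements a compact
    two-convolutional-layer neural network from first principles (forward and
    backward passes with a numeric-gradient verification oracle), extraction
    of normalized 32x32 region-of-interest patches from LIDC-style contour
    and centroid annotations, minibatch stochastic gradient descent with
    momentum and a precision-triggered learning-rate decay schedule, k-fold
    and fixed-holdout evaluation protocols reporting accuracy, sensitivity,
    false positives per exam and F-measure, and a synthetic patch generator
    emulating solid, semisolid and ground-glass nodules against vessel-like
    and background negatives so the whole pipeline is testable without any
    image download.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret,
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
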