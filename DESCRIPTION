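Package: dbtseg
Title: Mass-Region Segmentation in Digital Breast Tomosynthesis Volumes with
    a Dilated Fully Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for segmenting mass regions in digital
    breast tomosynthesis (DBT)-like grayscale slice stacks. Volumes are
    enhanced by a white top-hat transform combined with a multiplicative
    Gaussian radial-basis constraint matrix centred on candidate mass
    locations; a patch-based, class-balanced training scheme fits an
    eight-layer dilated fully convolutional network under a Dice
    (f-alpha-measure) loss; dense per-pixel two-class predictions are
    post-processed by small-cluster removal and binary median smoothing; and
    results are scored at pixel level (accuracy, sensitivity, specificity,
    ROC AUC) and lesion level (FROC). A seeded synthetic phantom generator
    provides DBT-like volumes with per-lesion ground truth so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
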