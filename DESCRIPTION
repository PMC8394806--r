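Package: cephan
Title: Automated Adenoid Hypertrophy Assessment from Lateral Cephalograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the four cephalometric keypoints (basion, articulare,
    the adenoid maximal-convexity point and the posterior nasal spine) in
    lateral-cephalogram-like images with a stacked-hourglass convolutional
    network featuring attention residual modules and soft-argmax integral
    regression, computes the Fujioka adenoid-nasopharyngeal (A/N) ratio from
    the detected landmarks, classifies adenoid hypertrophy at the 0.6
    threshold, and evaluates the whole pipeline with keypoint localization
    error, PCK-style average precision/recall, A/N ratio error, confusion
    metrics with Wilson confidence intervals, and ROC/AUC with bootstrap
    confidence intervals. A synthetic cephalogram generator with exact
    ground-truth landmarks makes the pipeline trainable and testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    pROC,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
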