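Package: earcount
Title: Tracking-by-Detection Counting of Wheat Ears in UAV Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting small, densely packed objects (wheat ears) in
    nadir UAV video by tracking-by-detection. Provides Gaussian-box modelling
    with the normalized Wasserstein distance similarity and loss for tiny
    objects, a space-to-depth feature-map rearrangement, a constant-velocity
    Kalman filter over box state, optimal Hungarian matching with IoU gating,
    a baseline-crossing counter that registers each tracked object once,
    detection and counting evaluation metrics (precision, recall, F1, average
    precision, R-squared, RMSE), and a synthetic camera-sweep scene generator
    with a configurable noisy detector for ground-truthed benchmarking.
    Detections are plain data frames in the MOT-challenge dialect, so any
    detector can feed the counter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
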