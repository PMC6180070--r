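Package: mwmtsa
Title: Trajectory Segmentation Analysis for the Morris Water Maze
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects behavioural strategies in Morris Water Maze swimming
    paths by splitting trajectories into overlapping constant-arc-length
    segments, computing geometric path features, classifying segments into
    nine exploration strategies with a semi-supervised constrained k-means
    (MPCK-Means) classifier ensemble gated by 10-fold cross-validation and
    combined by equal-weight majority voting, smoothing segment classes back
    onto full paths with a Gaussian-weighted interval vote, and comparing
    animal groups with Friedman tests and exact binomial confidence
    intervals.  Includes a seeded generator of stereotyped synthetic
    swimming paths for validation without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
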