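Package: nestwatch
Title: Quantifying Rodent Maternal Behavior from Home-Cage Pose Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A frame-level pipeline for scoring seven maternal behaviors
    (nest attendance, active and passive nursing, licking and grooming,
    self-directed grooming, eating, drinking) of rat dams in side-view
    home-cage recordings, starting from pose-estimation output rather than
    video. Reads single-animal dam keypoint tables and identity-free pup
    keypoint detections, joins them per frame, computes a 218-feature
    probability-weighted kinematic feature matrix (centroids, convex hulls,
    back-arch circle-fit angles, movement, rolling-window statistics,
    dam-pup distances), trains one binary random-forest classifier per
    behavior with precision-recall-curve threshold selection, converts
    frame labels to bouts and per-video summaries, and aggregates
    permutation-importance ranks and additive tree attributions by feature
    category. Includes a seeded simulator of home-cage sessions (scripted
    behavior bouts, posture templates, occlusion dropout) so the full
    pipeline is testable in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    data.table,
    xgboost,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
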