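Package: skewgait
Title: Video-Based Postural-Control Quantification from Pose Keypoints
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies postural control during walking from markerless
    pose-estimation output (OpenPose BODY_25 keypoint sequences). Builds
    dynamic joint-node plots by merging per-frame keypoint heatmaps, tracks
    the four corners of the per-frame body bounding box ("iso-block") across
    frames sampled at a fixed interval, fits four temporal-spatial
    least-squares regressions to the corner trajectories, and summarises each
    walk by the top and bottom slope-angle ratios (TAR, BAR) and walking
    velocity. Classifies straight, left-skewed and right-skewed walking with
    an RBF-kernel support vector machine under stratified cross-validation,
    and estimates feature cutting points by ROC analysis. Includes a
    synthetic gait generator (pinhole camera model of a 5 m walk toward or
    away from a static camera) so the full pipeline is testable without
    participant video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
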