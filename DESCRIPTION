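Package: gaitbalance
Title: Markerless Gait and Balance Analysis from 3D Keypoint Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes spatiotemporal gait parameters, knee kinematics,
    segmental centre-of-mass balance measures, reliability and validity
    statistics, and k-means++ balance-level stratification from 3D keypoint
    trajectories such as those produced by monocular video pose estimators.
    Includes preprocessing (sacrum centering, shank-length metric scaling,
    resampling, cross-correlation time alignment), gait event detection from
    knee angular velocity, an 11-segment whole-body centre-of-mass model,
    ICC(2,k) and Pearson validity reporting with conventional qualitative
    bands, Welch's t comparisons, and a parametric 17-joint gait simulator
    with recorded ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
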