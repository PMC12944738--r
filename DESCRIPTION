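Package: lpkin
Title: Vision-Based Landmine Press Velocity and Power Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for markerless velocity-based training analysis of the
    landmine press from oriented-bounding-box (OBB) video detections of the
    barbell's two ends. Converts per-frame OBB detections to a calibrated
    planar trajectory, computes rigid-body rotation kinematics (angle,
    angular velocity, tangential velocity, force and power) through a
    Savitzky-Golay / zero-phase Butterworth filtering chain, segments
    concentric phases and extracts per-repetition peak and mean velocity and
    power. Includes the full two-method agreement battery used in
    velocity-based training validation studies (Pearson correlation with
    interpretation bands, Bland-Altman limits of agreement with confidence
    intervals, paired t-test, paired Cohen's d, Deming regression with
    jackknife confidence intervals) and a synthetic trial generator with
    closed-form ground truth for fixture-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
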