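Package: kidmotion
Title: Validation Pipeline for Wearable IMU Versus Optical Motion Capture
Version: 0.1.0
Authors@R:
    person("KiD", "Motion Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate, process and validate paired recordings of
    sinusoidal arm movements captured simultaneously by a wrist-worn inertial
    measurement unit (IMU) and an optical motion-capture marker. The package
    rotates device-frame accelerometer samples into a fixed world frame using
    the on-board orientation quaternion, removes gravity, low-pass filters both
    modalities, synchronizes the two streams by cross-correlation of the
    acceleration magnitude, segments recordings into movement cycles,
    time-normalizes each cycle into percentage bins, quantifies inter-device
    agreement with two-way intraclass correlation coefficients (consistency and
    absolute agreement) including F-test significance, and classifies movement
    type (horizontal, vertical, elliptical, figure-eight) with a linear support
    vector machine under participant-structured nested cross-validation,
    cross-device cross-classification and a permutation null. A synthetic-data
    generator reproduces the statistical structure of the study design so the
    whole pipeline is testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
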