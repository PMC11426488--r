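Package: plumekin
Title: Odor-Plume Encounter Detection and Peri-Encounter Head-Motion Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for head-mounted sensor recordings from freely
    moving mice performing odor-guided search in a turbulent plume. Detects
    plume-encounter onsets from a metal-oxide gas-sensor voltage trace
    (low-pass filtering, difference-of-exponentials deconvolution, and
    cumulative-sum slope-ratio change detection), extracts head-motion
    spectral measures from a head-mounted 3-axis accelerometer (jerk,
    continuous wavelet transform band power, dominant frequency, and a
    Gaussian-mixture head-raised/lowered classifier), computes body- and
    head-angle kinematics from pose-estimation keypoints, and evaluates
    peri-encounter modulation against a surrogate (random-window) null with
    per-bin Kolmogorov-Smirnov tests and paired Wilcoxon tests on circular
    resultant-vector strengths. Includes a synthetic-trial generator with
    ground-truth encounter times for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
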