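Package: ocugate
Title: Ocular Biometric Gating and Baseline-Relative Depression-Pattern Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-module pre-drive screening pipeline for safety-critical
    transport settings. Module one performs Daugman-style iris identification:
    integro-differential boundary localisation on synthetic eye images,
    rubber-sheet normalisation, log-Gabor phase coding to 512- or 1024-bit iris
    codes, shift-tolerant fractional Hamming matching, and FAR/FRR/GAR/EER
    evaluation. Module two screens for depressive physiological response
    patterns: event-related pupillometry and gaze features (dilation amplitude,
    response latency, dilation velocity, fixation duration, saccade velocity
    and amplitude, gaze dispersion entropy, left-right asymmetry) are z-scored
    against each individual's multi-state baseline profile and classified by a
    2-standard-deviation deviation rule, a logistic feature model, and a
    random-convolution sequence classifier. A fully seeded synthetic-data
    generator supplies cohorts, pupil and gaze traces, eye images, and rater
    matrices; a gatekeeper module fuses identity and screening outcomes into a
    four-way access decision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
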