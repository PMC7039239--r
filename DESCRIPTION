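Package: gaitreid
Title: Person Re-Identification from Wearable Inertial Gait Signals
Version: 0.1.0
Authors@R:
    person("gaitreid", "developers", email = "gaitreid@example.org",
           role = c("aut", "cre"))
Description: Closed-set person re-identification from chest-worn
    six-channel inertial measurement unit (IMU) recordings of walking.
    Provides a synthetic quasi-periodic gait-signal simulator with
    per-subject harmonic signatures, fixed-grid step and stride window
    segmentation, robust (median/IQR) scaling, a from-scratch trainable
    bidirectional two-layer gated recurrent unit (GRU) classifier with a
    time-distributed softmax head, and re-identification evaluation
    protocols: cumulative matching characteristic (CMC) curves, rank-k
    accuracy, mean average precision, confusion matrices, subject-wise
    half splits and stratified k-fold cross-validation, plus cohort
    restriction by gender, age group and acquisition setup.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
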