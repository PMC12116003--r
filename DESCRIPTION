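Package: wearvo2
Title: Oxygen Uptake Prediction from Forearm EMG and IMU Wearable Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting second-by-second oxygen
    uptake (VO2, mL/kg/min) from a single forearm armband's 8-channel surface
    EMG (200 Hz) and 3-axis accelerometer/gyroscope (50 Hz) streams. Provides
    a synthetic cohort generator with first-order oxygen-uptake kinetics,
    CSV stream input/output with validation and time alignment, per-second
    statistical feature extraction (17 statistics over 17 raw channels plus
    lag/rolling features), Pearson-correlation and k-nearest-neighbour
    mutual-information feature selection, min-max scaling, from-scratch
    LSTM/BiLSTM/GRU sequence regressors trained with Adam and early stopping,
    leave-one-subject-out cross-validation with the standard regression
    metrics, and task-level oxygen-cost reporting with measured-versus-
    estimated comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
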