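Package: icurisk
Title: Dynamic Real-Time Mortality Risk Prediction for ICU Patients from
    Irregular Longitudinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dynamic, continuously updated in-hospital mortality
    risk prediction from irregular longitudinal intensive-care observations.
    Provides variable-dictionary-driven preprocessing (hourly discretization,
    per-variable aggregation, observation masks, time-since-last-observation
    encoding, an imputation cascade), static and rolling-horizon prediction
    tasks with patient-grouped splits, a time-aware bidirectional attention
    recurrent network (TBAL) with an LSTM baseline implemented natively,
    imbalance-aware training (balanced minibatches and a class-balance
    factor in the cross-entropy loss), integrated-gradients feature
    attribution, a bootstrap/subgroup/temporal evaluation suite, and a
    synthetic electronic-medical-record simulator that supplies ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
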