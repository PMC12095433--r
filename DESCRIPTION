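Package: surgecast
Title: Forecasting Daily Surgical Inpatient Bed Utilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for forecasting daily surgical inpatient
    bed occupancy from encounter-level operating-room data. Stage one predicts
    per-case postoperative length of stay with a random forest over case
    attributes and a truncated-SVD embedding of a sparse comorbidity-code
    matrix. Stage two forecasts daily surgical case volume with seasonal ARIMA
    models carrying a holiday exogenous regressor, identified from ACF/PACF
    diagnostics. Stage three aggregates per-case stays into daily bed-census
    arrays and evaluates SARIMAX, ordinary least squares and vector
    autoregression forecasters at long-term, two-week and same-day horizons
    under strict information cutoffs. A synthetic hospital-year generator with
    known ground truth drives testing and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
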