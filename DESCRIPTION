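Package: hemopred
Title: Postoperative Outcome Prediction from Intraoperative Hemodynamic
    Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An analysis pipeline for predicting binary postoperative
    outcomes (180-day mortality, acute renal failure) in major surgery from
    intraoperative hemodynamic monitoring records. Extracts per-signal
    waveform features (median, median absolute deviation, and
    time-integrated exposure area beyond a normal threshold), performs
    label-blind feature subset selection with column-pivoted QR under a
    matrix condition-number cap, exhaustively searches all
    logistic-regression classifiers of up to five features under
    leave-one-out cross-validation, and evaluates classifiers by ROC AUC
    with BCa bootstrap confidence intervals, DeLong paired comparisons and
    feature-inclusion-frequency summaries. Includes a synthetic cohort
    generator (autocorrelated multichannel waveforms, correlated
    preoperative laboratory values, outcomes from a logistic link) so the
    whole pipeline can be validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
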