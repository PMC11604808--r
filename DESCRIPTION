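Package: seizecast
Title: Seizure Forecasting from Raw Intracranial EEG with Stacked LSTM Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end framework for seizure prediction from raw,
    feature-engineering-free intracranial EEG. Ten-second segments of
    amplitude-normalized multichannel EEG are classified by a stacked
    long short-term memory (LSTM) network; five per-minute LSTM outputs
    are fused with nine cyclic time-of-day/week/month features and the
    log time since the last seizure by a small dense classifier.
    Includes a synthetic long-term iEEG generator (seizure cycles,
    pre-ictal signatures, telemetry dropouts, amplitude drift), a
    per-minute record store with EDF export, the 30-day rolling
    amplitude normalization and missing-data policy, lead-seizure
    labeling with tiered up-sampling and seizure-based train/test
    splits, and ROC/AUC evaluation with Hanley-McNeil confidence
    intervals, sensitivity/time-in-high operating points and
    multi-class confusion matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
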