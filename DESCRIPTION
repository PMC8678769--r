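Package: bptraj
Title: Latent-Group Trajectory Modelling of 24-Hour Post-Thrombolysis Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits group-based trajectory models (censored-normal latent-class
    mixtures of polynomial growth curves, estimated by EM) to serial blood
    pressure measurements recorded over the 24 hours after intravenous
    thrombolysis for acute ischaemic stroke. Provides model selection by
    information criteria with group-size and posterior-probability adequacy
    checks, classic blood-pressure variability summaries (mean, extremes,
    range, SD, successive variation over full-day and day/night windows),
    logistic-regression association of trajectory groups and BP parameters
    with early neurological deterioration, early neurological improvement and
    3-month functional outcome (odds ratios, Wald intervals, ROC AUC), and a
    calibrated synthetic cohort generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), pROC, mclust, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
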