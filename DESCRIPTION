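Package: taskCPCA
Title: Constrained Principal Component Analysis of Event-Related Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of task-evoked spatiotemporal components from
    parcellated BOLD time series by constrained principal component analysis
    (finite impulse response regression followed by a group-level singular
    value decomposition), event-locked response-curve estimation, multilevel
    growth modelling of component trajectories, brain-behaviour association
    of peak component scores with ranked task accuracy, and alignment of
    activation maps with regional structural difference maps via a
    mean-absolute-value statistic tested against spatial-autocorrelation
    preserving surrogate maps. Includes a synthetic-data generator that
    emulates a fast event-related emotion-identification task with known
    planted ground truth, so every stage of the pipeline can be validated
    by parameter recovery and null calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
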