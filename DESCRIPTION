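Package: gaitlrp
Title: Explainable Deep-Learning Classification of Running Gait Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for explainable classification of running-gait stance-phase
    waveforms. Simulates hierarchical two-class cohorts of joint-angle and
    joint-moment trajectories (subjects, trials, 18 trajectories time-normalized
    to 100 stance points), assembles kinematic/kinetic feature matrices with
    subject-grouped train/test splitting, trains fully-connected tanh deep
    neural networks, decomposes their predictions onto input features with
    Layer-wise Relevance Propagation (epsilon-stabilized z-rule), post-processes
    relevance into smoothed 0-1 contribution maps with top-k variable selection
    and joint/plane/phase contribution tables, and evaluates classifiers with a
    full confusion-matrix metric suite (accuracy, sensitivity, specificity,
    precision, F1, MCC, ROC/AUC). Includes stance-phase detection from vertical
    ground reaction force, zero-phase Butterworth filtering, time normalization,
    and hip-joint-center regression for signal preparation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
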