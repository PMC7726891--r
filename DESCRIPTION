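Package: ebbmetrics
Title: Balance-Board Array Gait Metrics and Functional Performance Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics pipeline for exergame sessions played on an extended
    balance board, an array of six consumer force platforms with four load
    sensors each sampled at 20 Hz. Fuses the 24 raw sensor channels into a
    weight-normalized centre-of-mass trajectory, classifies directional step
    intentions with a return-to-centre state machine, computes a per-sample
    instability factor and its rolling sum, and extracts a 42-dimensional
    per-playthrough feature vector covering directional centre-of-mass
    statistics, balance asymmetry, instability threshold exceedances and
    step-timing summaries. Includes XML playthrough-log reading and writing
    with corruption accounting, CSV/ARFF feature-table export, a synthetic
    gait simulator with controllable archetypes for end-to-end testing
    without hardware, and evaluation tools: chair-stand-test labelling,
    cross-validated threshold/tree/logistic classifiers, confusion-matrix
    metrics including the Matthews correlation coefficient, information-gain
    attribute ranking, and Hedges' g effect sizes with Welch t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    yaml,
    jsonlite,
    foreign,
    rpart
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
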