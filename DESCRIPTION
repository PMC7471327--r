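Package: facast
Title: Facility Attendance Forecasting from Medical Booking Histories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-label prediction of which medical facilities a patient
    will attend in the next nine weeks, from 52 weeks of administrative
    booking history. Implements booking-record ingestion and cleaning,
    per-patient weekly count matrices, provision clustering, facility
    ranking and regrouping, sliding-window extraction and labeling, a
    structured temporal convolutional neural network trained with the
    BP-MLL pairwise ranking loss, per-label threshold calibration,
    random-forest and multilayer-perceptron baselines, a full multi-label
    evaluation suite (Hamming distance, exact accuracy, per-label and
    pooled confusion metrics, AUC, first-access accuracy, attendance
    lower bounds), and a seeded synthetic booking-data generator so the
    whole pipeline is testable without access to administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    ranger
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
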