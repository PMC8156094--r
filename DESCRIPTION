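Package: tugfall
Title: Fall-Risk Screening from Wearable IMU Timed-Up-and-Go Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates, preprocesses and classifies wearable inertial
    measurement unit (IMU) recordings of the Timed-Up-and-Go (TUG)
    clinical mobility test to screen older adults for fall risk. Provides
    a labeled synthetic cohort generator with configurable gait effects,
    Fourier-domain resampling with cohort-wide min-max normalization and
    zero-padding, sliding-window segmentation, a one-dimensional
    convolutional neural network and a support vector machine classifier
    evaluated under a subject-level bootstrap-bagging protocol, and
    clinical screening statistics (confusion-matrix metrics, ROC/AUC with
    C-statistic inference, Youden-optimal cutoffs, and 2x2 odds ratios
    with Woolf confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    data.table,
    e1071,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
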