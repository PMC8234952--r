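Package: tensorecg
Title: Tensor-Based Unsupervised Anomaly Detection for Multi-Channel ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised detection of disease-altered heartbeats in
    multi-channel electrocardiogram (ECG) recordings. Each lead of a
    segmented beat is imaged with the Gramian Angular Difference Field
    (GADF), the per-lead images are stacked into a third-order tensor,
    multilinear principal component analysis (MPCA) compresses the tensor
    into a low-dimensional feature vector, and beats are scored either by
    one-class support vector data description (deep SVDD with a small
    bias-free neural network, or classic kernel SVDD) or monitored
    cycle-to-cycle with a Hotelling T-squared control chart calibrated on
    a patient's own normal beats. Includes a synthetic multi-lead ECG
    generator with parametric disease morphologies so the whole pipeline
    is testable without clinical data, plus WFDB-compatible and CSV
    readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
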