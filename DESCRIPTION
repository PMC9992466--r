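Package: ehrshift
Title: Temporal Robustness of EHR Foundation-Model Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying whether autoregressive
    foundation models over coded patient timelines (CLMBR-style clinical
    language model based representations) yield clinical prediction models
    that are more robust to temporal distribution shift than count-based
    baselines. Provides a synthetic electronic health record generator with
    controllable leaf-level code drift and ontology-invariant outcome
    signal, a medical-code ontology with ancestor extension and a
    hierarchical-sigmoid next-day code objective, GRU and transformer day
    sequence encoders, count-based featurization with clinical time bins,
    penalized logistic adaptation heads, and evaluation with AUROC,
    prevalence-calibrated AUPRC, absolute calibration error and bootstrap
    inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
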