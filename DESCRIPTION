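Package: cdindex
Title: Consciousness Domain Index from CRS-R Subscores
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives a binary Consciousness Domain Index (CDI) for patients
    with prolonged disorders of consciousness by clustering the six Coma
    Recovery Scale-Revised (CRS-R) subscores with K-means++ under five-fold
    twin-sample cross-validation, assigns external patients to clusters by
    nearest centroid, and evaluates the index against clinical diagnosis and
    CRS-R total-score cut-offs as predictors of recovery of full
    consciousness, via contingency analyses and a multivariate
    logistic-regression battery.  A calibrated synthetic-cohort generator
    makes the full pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
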