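Package: digitalCTC
Title: Digital PCR Quantification and Multi-Marker Scoring of Circulating
    Tumor Cell Biomarkers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiplex real-time digital PCR (dPCR)
    quantification of circulating tumor cell (CTC) protein-surrogate oligo
    tags and mRNAs. Provides per-microwell amplification-curve fitting with
    Ct and fluorescence-growth-rate extraction and positive/negative well
    calling; Poisson absolute quantification from partition counts with
    confidence intervals; assay analytics (nonparametric limit of blank,
    probit limit of detection, percent CV, standard curves, amplification
    efficiency); an AHP-weighted multi-marker composite Z-score for
    hepatocellular carcinoma diagnosis with logistic combination and ROC
    analysis; 2D protein-mRNA molecular profiling with ASGPR calibration,
    support-vector region assignment and treatment efficacy vectors; and a
    seeded plate/cohort simulator so the full workflow is testable with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    e1071,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Classification, ddPCR
RoxygenNote: 7.3.3
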