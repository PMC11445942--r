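Package: arfpheno
Title: Phenotyping Sepsis-Induced Acute Respiratory Failure from EMR Event Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for deriving and validating data-driven phenotypes of
    sepsis-induced acute respiratory failure from timestamped electronic-medical-record
    event streams. Implements rule-based sepsis-3 onset detection from six-organ SOFA
    scoring, cohort construction around the index of invasive mechanical ventilation,
    pre-intubation feature engineering (median aggregation, outlier handling,
    chained-equation imputation, correlation pruning, scaling), unsupervised phenotype
    derivation by embedding (UMAP or PCA) plus k-means with internal-validity model
    selection, cluster characterization and canonical phenotype labeling, a frozen
    transfer classifier for external cohorts, 28-day survival and ventilator-free-day
    outcomes, and propensity-matched estimation of high-PEEP treatment effects. A
    synthetic multi-phenotype EHR cohort generator makes every stage testable without
    access to protected clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival,
    nnet,
    uwot,
    xgboost,
    glmnet,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
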