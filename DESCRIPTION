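Package: markergrid
Title: Comparative Biomarker Panel Refinement with Nested Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative framework for case-control transcriptome
    classification and biomarker panel refinement. Combines five unsupervised
    pre-filters (interquartile-range, probe-consistency, intensity-threshold,
    one-factor informativeness, and rule-chain filters), moderated-t
    differential expression with empirical-Bayes variance shrinkage, five
    ranking-and-filtering rules (including an SVM-weight reduction step), and
    eight probability-returning classifiers, all evaluated with
    multiple-partition stratified nested cross-validation, one-standard-error
    model selection and optimism bias correction. Includes RMA-style
    quantile-normalization and median-polish summarization of probe-level
    data, cross-panel feature-inclusion aggregation, and hypergeometric
    gene-set enrichment, plus a synthetic cohort generator emulating a
    balanced 24 vs 24 case-control microarray study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma,
    glmnet,
    MASS,
    e1071,
    randomForest,
    xgboost,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
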