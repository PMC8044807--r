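Package: enrichprs
Title: Systems-Biology-Guided Polygenic Risk Scores for Chronic
    Post-Surgical Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and evaluates polygenic risk scores (PRS) for
    chronic post-surgical pain (CPSP) in small, prospectively recruited
    surgical cohorts where genome-wide association is underpowered.
    Implements variant quality control (call rate, Hardy-Weinberg,
    minor-allele frequency, sliding-window LD pruning), covariate-adjusted
    additive association with a continuous pain outcome, cumulative
    decile gene-set enrichment tested against minor-allele-frequency
    matched resampling nulls with empirical p-values, dual L1-penalized
    (linear and logistic LASSO) variant selection, weighted PRS
    construction, stepwise logistic prediction models with DeLong AUC
    comparison, bootstrap bias-corrected internal validation, and the
    accompanying power calculations. A synthetic cohort generator with
    planted genetic effects makes the full pipeline testable end to end
    without access to restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    methods,
    pROC,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
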