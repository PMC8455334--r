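Package: netsig
Title: Network-Guided Blood Transcriptome Signatures of Growth Hormone
    Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for discovering blood
    gene-expression signatures that classify year-by-year growth response
    to recombinant human growth hormone in growth hormone deficiency and
    Turner syndrome. Implements covariate-eliminated rank-regression and
    Kruskal-Wallis association scans with LD-block-aware multiple-testing
    correction, seed-gene interactome models with overlapping module
    detection on an influence landscape and metanode core extraction,
    cross-condition signature selection with hypergeometric overlap
    testing, random-forest classification with SMOTE rebalancing,
    Boruta-style shadow-feature confirmation, PLS-DA and DAPC ordinations,
    gene-level methylation mapping, and a synthetic-cohort generator with
    planted ground truth for end-to-end recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    mclust,
    pROC,
    randomForest,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
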