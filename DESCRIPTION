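Package: methylaging
Title: Cross-Species DNA Methylation Aging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of DNA methylation and aging
    across species. Provides an elastic-net epigenetic clock with
    leave-one-out and leave-one-species-out cross-validation, meta-analytic
    discovery of age-associated differentially methylated positions by
    Stouffer combination of per-species correlations, phylogenetic
    generalized least squares regression of longevity on mean methylation
    rate under Brownian covariance, per-site linear mixed models with an
    age-by-longevity-class interaction corrected by Benjamini-Yekutieli
    FDR, gene and region enrichment tests, and a synthetic-data generator
    that emulates lifespan-dependent methylation drift on a phylogeny with
    ground-truth labels for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    ape,
    jsonlite,
    limma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
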