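Package: panelfinder
Title: Discovery and Small-Sample Validation of Transcriptomic Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering and validating compact
    gene-expression biomarker panels in small cohorts. Covers two-group
    differential expression (moderated t, exact Wilcoxon rank-sum,
    Benjamini-Hochberg FDR), preranked gene-set enrichment with a weighted
    Kolmogorov-Smirnov-like statistic, weighted co-expression modules
    (soft thresholding, topological overlap, eigengenes, module-trait
    correlation), hub-gene consensus over eleven network centralities,
    sparse panel selection by L1-penalized logistic regression, and
    leakage-free validation via nested cross-validation with Firth
    penalized logistic regression and a safe stratified 0.632+ bootstrap
    with a matched permutation null. Includes a synthetic-data generator
    with planted differential genes, latent-factor co-expression modules
    and probe multiplicity, so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
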