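Package: igesel
Title: Integrative Gene-Environment Interaction Analysis with Multi-Omics
    Regulatory Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage penalized variable selection for gene-environment
    (GxE) interaction studies that integrates gene expression with its
    upstream regulators (DNA methylation and copy number alteration).
    Stage 1 estimates a sparse regulator-to-expression transition matrix
    by per-gene LASSO and decomposes it into linear regulatory models
    (LRMs) via recursive rank-1 sparse singular value decomposition.
    Stage 2 fits a sparse group LASSO GxE model on the regulated
    expression components, residual expressions and their environmental
    interactions, and residual regulators. Includes a simulator for the
    benchmarked data-generating designs, single-stage LASSO baselines,
    and ROC / partial-AUC machinery for selection accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
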