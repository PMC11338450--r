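Package: rnmfimpute
Title: Robust Graph-Regularized Non-Negative Matrix Factorization for
    Single-Cell RNA-Seq Dropout Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes dropout zeros in single-cell RNA-seq count matrices by
    robust non-negative matrix factorization. Observed (non-zero) entries are
    fitted under a quadratic loss while zero entries, which may be technical
    dropouts rather than biological zeros, are fitted under a bounded
    correntropy-induced loss that saturates for large residuals. Gene-gene and
    cell-cell similarity graphs regularize the factor matrices, and the
    non-convex objective is minimized by half-quadratic alternation with
    multiplicative updates. Includes median-library log normalization and
    highly variable gene selection, masked-entry random hyperparameter search,
    a group-structured synthetic count simulator with mean-dependent logistic
    dropout, clustering and recovery evaluation metrics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    optparse,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
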