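Package: scmodules
Title: Cross-Batch Discovery and Validation of Gene Activity Modules in
    Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers gene expression programs in multi-batch single-cell
    RNA-seq count data by per-batch consensus non-negative matrix
    factorization, matches programs across batches by Jaccard similarity to
    extract cross-batch consensus gene modules, and validates them with a
    battery of statistics: rank-based (Mann-Whitney U) per-cell module
    scoring, bulk mean-z scoring, longitudinal trend regression,
    correlation and permutation nulls, Kolmogorov-Smirnov comparisons,
    quartile stratification, ligand-receptor pairing, enrichment tests and
    gene-set disease classification. Ships a synthetic-data generator with
    a ground-truth channel so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tools,
    methods,
    stats,
    utils,
    cluster,
    statmod,
    pracma,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
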