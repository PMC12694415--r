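Package: plaidr
Title: Ultrafast Single-Sample Gene Set Enrichment Scoring via Sparse
    Cross-Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample gene set enrichment scoring for bulk and
    single-cell omics data. Scores a gene set in each sample as the average
    log-intensity of its member features, computed as a single sparse matrix
    cross-product between a column-normalized gene-set indicator matrix and
    the expression matrix, with automatic chunking over sample columns for
    very large inputs and median normalization of the resulting score matrix.
    Also provides a replication suite that recasts six established
    single-sample scoring methods (singscore, scSE, ssGSEA, GSVA, UCell,
    AUCell) as per-gene rank transforms aggregated through the same sparse
    back-end, GMT and MatrixMarket input/output, deterministic synthetic
    fixture generators with spike-in signatures, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
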