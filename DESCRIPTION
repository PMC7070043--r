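Package: dexhet
Title: Single-Cell Heterogeneity of the Glucocorticoid Transcriptional Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of cell-to-cell heterogeneity in the
    transcriptional response to glucocorticoids, as measured by single-cell
    RNA-seq across a dexamethasone treatment time course. Provides a
    negative-binomial count simulator with expression-dependent dropout and
    stochastic per-cell responder structure; a tagged-read demultiplexer with
    Hamming-distance barcode correction, knee-based cell calling and per-gene
    UMI deduplication; QC, balanced downsampling, log normalization and
    covariate-regression scaling; a two-part (hurdle) differential expression
    test with fold-change, FDR and detection cutoffs; per-cell Ratio of
    Responding Genes (RRG) and per-gene Responding-Cell percentage (RC%)
    statistics against an SD threshold over vehicle-treated cells; and a
    gene-gene correlation analysis calibrated by an expression-matched
    resampling null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
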