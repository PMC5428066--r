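Package: lendex
Title: Gene-Length-Dependent Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and quantifying gene-length-dependent
    misexpression in transcriptomes. Computes length-ordered sliding-window
    fold-change curves, permutation-shuffle null envelopes for pointwise
    significance, and threshold-based tests that differentially expressed
    gene sets are length-shifted relative to all genes. Includes platform
    normalization steps (probe collapsing, exon-density normalization,
    quantile normalization), GTF-derived gene lengths, a synthetic-data
    generator with planted length effects and cell-type mixture shifts, and
    an end-to-end pipeline driver with a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'lendex-package.R'
    'AllClasses.R'
    'accessors.R'
    'foldchange.R'
    'bootstrap.R'
    'simulate.R'
    'detest.R'
    'pipeline.R'
    'cli.R'
    'io.R'
    'normalization.R'
    'utils.R'
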