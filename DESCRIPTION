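Package: coopdeg
Title: Differential Expression, Cross-Contrast Concordance, and Genomic
    Clustering of Gene Sets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparative bulk RNA-seq differential expression
    between a mutant and control condition and across companion contrasts.
    Implements RPKM computation, signed fold changes under the
    negative-reciprocal convention, two-tailed t-tests with
    Benjamini-Hochberg correction, threshold-based developmental calls,
    six-way expression-level classification of differentially expressed
    genes, Pearson and quadrant concordance summaries between contrasts,
    permutation tests for genomic clustering of gene sets, hypergeometric
    term overrepresentation, promoter-window motif copy counting, and
    delta-delta-Ct qPCR validation arithmetic. A fully specified
    synthetic-data generator with a recorded truth table makes every stage
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
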