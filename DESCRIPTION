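Package: snvadapt
Title: Data-Adaptive Probabilistic Single Nucleotide Variant Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls single nucleotide variants with an empirical,
    data-adaptive score. Per-site log-odds components for base quality,
    relative read position, per-read alignment errors and alignment
    multiplicity are estimated from a background sample of low-mismatch
    sites, combined with the empirical quantile of the site mismatch
    rate, and thresholded at the leftmost local minimum of a
    Poisson-spline density fitted to the histogram of positive scores
    (with an upper-quantile fallback when no minimum exists). Includes a
    pileup engine built on Rsamtools, a VCF writer built on
    VariantAnnotation, and a read simulator with controllable variant
    allele fraction, coverage and error structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    splines,
    stats,
    utils,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    VariantAnnotation,
    rtracklayer,
    BiocGenerics,
    SummarizedExperiment,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
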