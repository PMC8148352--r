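Package: tdfe
Title: Tensor-Decomposition-Based Unsupervised Feature Extraction for
    Mitotic Histone-Modification Bookmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a five-mode tensor of genome-binned histone-modification
    ChIP-seq signal across cell lines, marks, cell-cycle phases and
    replicates, decomposes it by higher-order singular value decomposition
    (HOSVD), and selects genomic regions whose modification pattern shows
    mitotic transcription reactivation (high in interphase and
    anaphase/telophase, low in prometaphase for H3K27ac) together with
    bookmark-like, phase-constant H3K4 methylation.  Region significance is
    assigned from a chi-squared test on the region-mode singular vector under
    a Gaussian null with Benjamini-Hochberg correction.  Includes Welch
    t-test validation of the reactivation/bookmark pattern, gene annotation
    and stepwise peak-overlap utilities, and a synthetic-data generator that
    plants bookmark regions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
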