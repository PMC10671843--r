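Package: dsbmotifs
Title: Permutation Analysis of Degenerate Motif Enrichment at
    Structural-Variant Breakpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Enumerates the concrete sequence variants of a degenerate
    IUPAC DNA motif (by default the 13-bp PRDM9 zinc-finger recognition
    motif CCNCCNTNNCCNC), locates every occurrence of each variant in a
    genome assembly, and tests whether occurrences are enriched in
    fixed-width windows centered on double-strand-break coordinates using
    a region-randomization permutation test with empirical p-values,
    z-scores, and a positional-displacement (local z-score) control.
    Variants significant across breakpoint sets are summarized into an
    IUPAC consensus motif. A synthetic-data generator produces genomes
    with planted motif occurrences and breakpoint sets with controlled
    enrichment, so every stage of the pipeline is testable without
    external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
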