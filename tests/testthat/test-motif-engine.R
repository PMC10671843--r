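test_that("degenerate expansion enumerates all variants in lexicographic order", {
    v <- expandDegenerate(PRDM9_MOTIF)
    expect_length(v, 1024L)
    expect_length(unique(as.character(v)), 1024L)
    expect_identical(names(v), as.character(1:1024))
    # every expansion matches the pattern position-wise
    expect_true(all(grepl("^CC[ACGT]CC[ACGT]T[ACGT][ACGT]CC[ACGT]C$",
                          as.character(v))))
    # lexicographic: sorted order equals enumeration order
    expect_identical(as.character(v), sort(as.character(v)))

    expect_identical(unname(as.character(expandDegenerate("ACGT"))), "ACGT")
    expect_identical(unname(as.character(expandDegenerate("ANT"))),
                     c("AAT", "ACT", "AGT", "ATT"))
})

test_that("cardinality is the product of position set sizes", {
    expect_equal(motifCardinality("CCNCCNTNNCCNC"), 1024)
    expect_equal(motifCardinality("ACGT"), 1)
    expect_equal(motifCardinality("RYN"), 2 * 2 * 4)
    set.seed(11)
    codes <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")
    for (i in 1:10) {
        pat <- paste(sample(codes, sample(1:6, 1), replace = TRUE),
                     collapse = "")
        expect_length(expandDegenerate(pat), motifCardinality(pat))
    }
})

test_that("invalid IUPAC characters are rejected with their position", {
    expect_error(expandDegenerate("AXT"), "'X' at position 2")
    expect_error(scanMotif(GenomeAssembly(c(chr1 = 10L)), "A!T"),
                 "position 2")  # pattern validated before the sequence check
    expect_error(expandDegenerate(""), "non-empty")
})

test_that("scanMotif finds exact occurrences, including overlapping ones", {
    asm <- assemblyFromSequences(c(chr1 = "CCACCATCACCACAA"))
    hits <- scanMotif(asm, "CCACCATCACCAC")
    expect_length(hits, 1L)
    expect_equal(GenomicRanges::start(hits) - 1L, 0L)
    expect_equal(GenomicRanges::end(hits), 13L)

    expect_length(scanMotif(assemblyFromSequences(c(chr1 = "AAAAAA")), "CCC"), 0L)

    hits2 <- scanMotif(assemblyFromSequences(c(chr1 = "CCCC")), "CC")
    expect_equal(GenomicRanges::start(hits2) - 1L, bruteScan("CCCC", "CC"))
})

test_that("scan agrees with the sliding-window oracle on random sequences", {
    set.seed(7)
    for (i in 1:20) {
        seq <- randomSeq(400, gc = 0.6)
        asm <- assemblyFromSequences(c(chr1 = seq))
        pat <- substr(randomSeq(5), 1, sample(2:4, 1))
        hits <- scanMotif(asm, pat)
        expect_equal(GenomicRanges::start(hits) - 1L, bruteScan(seq, pat),
                     info = paste("pattern", pat))
    }
})

test_that("reported intervals re-extract to the variant sequence; N never matches", {
    set.seed(8)
    seq <- paste0(randomSeq(200), "NNNNN", randomSeq(200))
    asm <- assemblyFromSequences(c(chr1 = seq))
    pat <- "CAG"
    hits <- scanMotif(asm, pat)
    if (length(hits) > 0) {
        got <- as.character(Biostrings::extractAt(
            genomeSequence(asm)[[1]],
            IRanges::IRanges(GenomicRanges::start(hits),
                             GenomicRanges::end(hits))))
        expect_true(all(got == pat))
    }
    # a pattern straddling the mask is never reported
    asmN <- assemblyFromSequences(c(chr1 = "CCNCC"))
    expect_length(scanMotif(asmN, "CNC"), 0L)
    expect_length(scanMotif(asmN, "CCNCC"), 0L)
})

test_that("scan results are invariant to FASTA line wrapping", {
    set.seed(9)
    seq <- randomSeq(500)
    a1 <- readGenomeFasta(writeTempFasta(list(chr1 = seq)))
    a2 <- readGenomeFasta(writeTempFasta(list(chr1 = seq), wrap = 37))
    h1 <- scanMotif(a1, "CCAC")
    h2 <- scanMotif(a2, "CCAC")
    expect_identical(GenomicRanges::start(h1), GenomicRanges::start(h2))
})

test_that("both-strand mode adds reverse-complement matches on forward coordinates", {
    # GAATTC is its own reverse complement: both mode must not double-count
    asm <- assemblyFromSequences(c(chr1 = "AAGAATTCAA"))
    expect_length(scanMotif(asm, "GAATTC", strandMode = "both"), 1L)
    # CCCAAA: reverse complement TTTGGG absent forward, present as rc
    asm2 <- assemblyFromSequences(c(chr1 = "TTTGGGTT"))
    expect_length(scanMotif(asm2, "CCCAAA"), 0L)
    fb <- scanMotif(asm2, "CCCAAA", strandMode = "both")
    expect_equal(GenomicRanges::start(fb) - 1L, 0L)  # forward coordinates
})

test_that("variant longer than every chromosome warns and returns empty", {
    asm <- assemblyFromSequences(c(chr1 = "ACGT"))
    expect_warning(hits <- scanMotif(asm, "ACGTACGT"), "longer")
    expect_length(hits, 0L)
    expect_error(scanMotif(GenomeAssembly(c(chr1 = 100L)), "ACG"),
                 "no sequence")
})

test_that("per-variant scans partition the degenerate scan (worked example)", {
    asm <- assemblyFromSequences(c(chr1 = "CACCGC"))
    scan <- scanAllVariants(asm, "CNC")
    man <- scan$manifest
    expect_identical(man$sequence, c("CAC", "CCC", "CGC", "CTC"))
    expect_equal(man$n_hits, c(1L, 0L, 1L, 0L))
    expect_equal(GenomicRanges::start(scan$union) - 1L, c(0L, 3L))
    expect_equal(GenomicRanges::end(scan$union), c(3L, 6L))
})

test_that("all-N sequence yields no hits for any variant", {
    asm <- assemblyFromSequences(c(chr1 = strrep("N", 50)))
    scan <- scanAllVariants(asm, "CNC")
    expect_true(all(scan$manifest$n_hits == 0L))
    expect_length(scan$union, 0L)
})

test_that("union of per-variant hits equals the degenerate-pattern scan", {
    set.seed(10)
    for (i in 1:25) {
        asm <- assemblyFromSequences(c(chr1 = randomSeq(1000, gc = 0.55)))
        scan <- scanAllVariants(asm, "CCNC")
        direct <- scanMotif(asm, "CCNC")
        expect_identical(GenomicRanges::start(scan$union),
                         GenomicRanges::start(direct))
        expect_equal(sum(scan$manifest$n_hits), length(direct))
    }
})
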