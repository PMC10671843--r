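test_that("config validation catches impossible setups", {
    expect_error(syntheticConfig(gcContent = 0), "gcContent")
    expect_error(syntheticConfig(enrichmentFraction = 1.5), "enrichmentFraction")
    expect_error(syntheticConfig(plantedVariant = "CCACCATCACCAA"),
                 "not an expansion")  # last position must be C
    expect_error(syntheticConfig(plantedVariant = "CCAC"), "length")
    expect_error(syntheticConfig(nChroms = 1, chromLength = 1000,
                                 nPlantedSites = 100), "cover too much")
})

test_that("genome generation is deterministic and plants recoverable sites", {
    cfg <- syntheticConfig(nChroms = 2L, chromLength = 50000L,
                           nPlantedSites = 50L, seed = 21)
    g1 <- generateGenome(cfg)
    g2 <- generateGenome(cfg)
    expect_identical(as.character(genomeSequence(g1$assembly)),
                     as.character(genomeSequence(g2$assembly)))
    expect_identical(GenomicRanges::start(g1$truthSites),
                     GenomicRanges::start(g2$truthSites))
    expect_length(g1$truthSites, 50L)
    # truth sites are non-overlapping and re-extract to the planted variant
    expect_true(all(GenomicRanges::countOverlaps(g1$truthSites,
                                                 g1$truthSites) == 1L))
    hits <- scanMotif(g1$assembly, cfg$plantedVariant)
    ov <- GenomicRanges::countOverlaps(g1$truthSites, hits,
                                       type = "equal")
    expect_true(all(ov >= 1L))
})

test_that("background composition matches the requested GC content", {
    cfg <- syntheticConfig(nChroms = 1L, chromLength = 1000000L,
                           gcContent = 0.5, nPlantedSites = 0L, seed = 8)
    g <- generateGenome(cfg)
    freq <- Biostrings::letterFrequency(genomeSequence(g$assembly), "GC",
                                        as.prob = TRUE)
    expect_lt(abs(freq[1] - 0.5), 0.005)
})

test_that("breakpoints honour the enrichment contract at both extremes", {
    cfg1 <- syntheticConfig(nChroms = 2L, chromLength = 100000L,
                            nPlantedSites = 40L, nBreakpoints = 200L,
                            enrichmentFraction = 1, proximityDistance = 10L,
                            seed = 31)
    g <- generateGenome(cfg1)
    bp <- generateBreakpoints(cfg1, g$truthSites, g$assembly)
    expect_true(all(S4Vectors::mcols(bp)$enriched))
    centers <- GenomicRanges::resize(g$truthSites, 1L, fix = "center")
    d <- GenomicRanges::distanceToNearest(bp, centers)
    expect_true(all(S4Vectors::mcols(d)$distance <= 10L))

    # f = 0: fraction near sites matches the uniform coverage expectation
    cfg0 <- syntheticConfig(nChroms = 2L, chromLength = 2500000L,
                            nPlantedSites = 500L, nBreakpoints = 2000L,
                            enrichmentFraction = 0, proximityDistance = 50L,
                            seed = 32)
    g0 <- generateGenome(cfg0)
    bp0set <- generateBreakpoints(cfg0, g0$truthSites, g0$assembly)
    expect_true(all(!S4Vectors::mcols(bp0set)$enriched))
    near <- GenomicRanges::countOverlaps(
        bp0set, suppressWarnings(GenomicRanges::trim(GenomicRanges::resize(
            g0$truthSites, 101L, fix = "center"))))
    pcov <- 500 * 101 / 5e6
    frac <- mean(near > 0)
    expect_lt(abs(frac - pcov), 3 * sqrt(pcov * (1 - pcov) / 2000) + 0.002)

    expect_error(generateBreakpoints(
        syntheticConfig(enrichmentFraction = 0.5, nPlantedSites = 0L),
        GenomicRanges::GRanges(), g$assembly), "planted sites")
})

test_that("breakpoint generation is deterministic given its seed", {
    cfg <- syntheticConfig(nChroms = 1L, chromLength = 100000L,
                           nPlantedSites = 20L, nBreakpoints = 50L,
                           enrichmentFraction = 0.5, seed = 77)
    g <- generateGenome(cfg)
    b1 <- generateBreakpoints(cfg, g$truthSites, g$assembly)
    b2 <- generateBreakpoints(cfg, g$truthSites, g$assembly)
    expect_identical(GenomicRanges::start(b1), GenomicRanges::start(b2))
    b3 <- generateBreakpoints(cfg, g$truthSites, g$assembly, seed = 1234)
    expect_false(identical(GenomicRanges::start(b1),
                           GenomicRanges::start(b3)))
})

test_that("the study fixture writes the documented bundle reproducibly", {
    dir1 <- tempfile("fixture1_")
    dir2 <- tempfile("fixture2_")
    cfg <- syntheticConfig(nChroms = 3L, chromLength = 200000L,
                           nPlantedSites = 60L, seed = 11)
    fx1 <- makeStudyFixture(dir1, studyProfile(), cfg)
    fx2 <- makeStudyFixture(dir2, studyProfile(), cfg)

    labels <- c("BRC", "LUAD", "OV", "HN")
    sizes <- c(BRC = 150L, LUAD = 170L, OV = 230L, HN = 170L)
    for (lab in labels) {
        bed <- file.path(dir1, paste0(lab, ".breakpoints.bed"))
        expect_true(file.exists(bed))
        expect_length(readLines(bed), sizes[[lab]])
    }
    expect_equal(sum(vapply(labels, function(lab)
        length(fx1$breakpointSets[[lab]]), integer(1))), 720L)

    # byte-identical bundle on re-run with the same seed
    for (f in list.files(dir1)) {
        expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                         unname(tools::md5sum(file.path(dir2, f))),
                         info = f)
    }
    # outputs pass their own validation round-trip
    asm <- readGenomeFasta(file.path(dir1, "genome.fa"))
    sizesTab <- readChromSizes(file.path(dir1, "genome.chrom.sizes"))
    expect_identical(chromLengths(asm), chromLengths(sizesTab))
    truth <- readBed(file.path(dir1, "truth_sites.bed"), asm)
    expect_length(truth, 60L)
    for (lab in labels)
        expect_length(readBed(file.path(dir1,
            paste0(lab, ".breakpoints.bed")), asm), sizes[[lab]])
})
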