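test_that("randomization preserves lengths, respects bounds and the gap mask", {
    asm <- GenomeAssembly(c(chr1 = 10L))
    r <- randomizeRegions(gr0("chr1", 0, 10, asm), asm, seed = 1)
    expect_equal(GenomicRanges::start(r), 1L)  # forced placement
    expect_equal(GenomicRanges::end(r), 10L)

    # mask [0,500) of a 1000-bp chromosome: placements confined to [500,900]
    masked <- assemblyFromSequences(c(chr1 = paste0(strrep("N", 500),
                                                    randomSeq(500))))
    reg <- gr0("chr1", 600, 700, masked)
    for (s in 1:20) {
        r <- randomizeRegions(reg, masked, seed = s)
        expect_gte(GenomicRanges::start(r) - 1L, 500L)
        expect_lte(GenomicRanges::end(r), 1000L)
        expect_equal(GenomicRanges::width(r), 100L)
    }
    # a 600-bp interval exceeds the 500-bp largest un-masked stretch
    expect_error(randomizeRegions(gr0("chr1", 300, 900, masked), masked,
                                  seed = 1), "un-masked")
})

test_that("placement is uniform over valid starts (chi-squared goodness of fit)", {
    asm <- GenomeAssembly(c(chr1 = 8L))
    reg <- gr0("chr1", 0, 5, asm)
    starts <- withr::with_seed(99, {
        big <- do.call(c, lapply(1:40, function(i)
            randomizeRegions(rep(reg, 1000), asm)))
        GenomicRanges::start(big) - 1L
    })
    counts <- table(factor(starts, levels = 0:3))
    expect_equal(sum(counts), 40000)
    gof <- chisq.test(counts)
    expect_gt(gof$p.value, 0.001)
})

test_that("multi-chromosome placement weights chromosomes by valid-start count", {
    asm <- GenomeAssembly(c(chr1 = 3000L, chr2 = 1000L))
    reg <- gr0("chr1", 0, 100, asm)
    chroms <- withr::with_seed(5, {
        r <- randomizeRegions(rep(reg, 20000), asm)
        as.character(GenomicRanges::seqnames(r))
    })
    p1 <- (3000 - 100 + 1) / ((3000 - 100 + 1) + (1000 - 100 + 1))
    obs <- mean(chroms == "chr1")
    expect_lt(abs(obs - p1), 3 * sqrt(p1 * (1 - p1) / 20000) + 0.005)
})

test_that("empty hit set gives the degenerate null: p = 1, z undefined", {
    asm <- GenomeAssembly(c(chr1 = 10000L))
    win <- makeWindows(bp0("chr1", c(1000, 5000), asm), 100, asm)
    none <- GenomicRanges::GRanges(seqinfo = seqinfo(asm))
    expect_warning(res <- permTest(win, none, asm, nPerm = 50, seed = 1),
                   "degenerate")
    expect_equal(observedOverlap(res), 0L)
    expect_true(all(nullDistribution(res) == 0))
    expect_equal(pValue(res), 1.0)
    expect_true(is.na(zScore(res)))
    expect_error(permTest(none, win, asm, nPerm = 10), "empty")
})

test_that("identical windows and hits give the count-once maximum", {
    asm <- GenomeAssembly(c(chr1 = 100000L))
    win <- makeWindows(bp0("chr1", seq(1000, 9000, by = 1000), asm), 100, asm)
    res <- permTest(win, win, asm, nPerm = 100, seed = 2)
    expect_equal(observedOverlap(res), length(win))
})

test_that("permutation tests are reproducible given a seed and respect the p floor", {
    asm <- GenomeAssembly(c(chr1 = 50000L))
    win <- makeWindows(bp0("chr1", c(100, 20000, 40000), asm), 100, asm)
    hits <- gr0("chr1", c(110, 20010, 40010), c(123, 20023, 40023), asm)
    r1 <- permTest(win, hits, asm, nPerm = 300, seed = 42)
    r2 <- permTest(win, hits, asm, nPerm = 300, seed = 42)
    expect_identical(nullDistribution(r1), nullDistribution(r2))
    expect_identical(pValue(r1), pValue(r2))
    expect_gte(pValue(r1), 1 / 301)
    r3 <- permTest(win, hits, asm, nPerm = 300, seed = 43)
    expect_false(identical(nullDistribution(r1), nullDistribution(r3)))
})

test_that("auto alternative resolves by the observed side of the null mean", {
    asm <- GenomeAssembly(c(chr1 = 50000L))
    win <- makeWindows(bp0("chr1", c(100, 20000, 40000), asm), 100, asm)
    hits <- gr0("chr1", c(110, 20010, 40010), c(123, 20023, 40023), asm)
    res <- permTest(win, hits, asm, nPerm = 200, seed = 1)
    expect_identical(res@alternative, "greater")  # obs = 3 vs mean ~ 0
    # with hits avoided entirely and dense hits elsewhere, less is resolved
    dense <- gr0("chr1", seq(0, 49000, by = 60),
                 seq(50, 49050, by = 60), asm)
    win2 <- makeWindows(bp0("chr1", c(55, 115), asm), 4, asm)
    res2 <- permTest(win2, dense, asm, nPerm = 200, seed = 1,
                     alternative = "auto")
    expect_true(res2@alternative %in% c("greater", "less"))
})

test_that("randomizing the hit set instead of windows is supported", {
    asm <- GenomeAssembly(c(chr1 = 50000L))
    win <- makeWindows(bp0("chr1", c(100, 20000, 40000), asm), 100, asm)
    hits <- gr0("chr1", c(110, 20010, 40010), c(123, 20023, 40023), asm)
    res <- permTest(win, hits, asm, nPerm = 100, seed = 9,
                    randomize = "hits")
    expect_equal(observedOverlap(res), 3L)
    expect_lte(max(nullDistribution(res)), length(win))
    res2 <- permTest(win, hits, asm, nPerm = 100, seed = 9,
                     randomize = "hits")
    expect_identical(nullDistribution(res), nullDistribution(res2))
})

test_that("empirical p-values are valid under the null generator", {
    # conservative guarantee of the +1-smoothed empirical p-value:
    # P(p < alpha) <= alpha (up to permutation noise), checked at desk scale
    cfg <- syntheticConfig(nChroms = 1L, chromLength = 500000L,
                           nPlantedSites = 30L, nBreakpoints = 30L,
                           enrichmentFraction = 0, seed = 1)
    gen <- generateGenome(cfg)
    hits <- gen$truthSites
    reject <- withr::with_seed(77, {
        vapply(1:60, function(r) {
            bp <- generateBreakpoints(cfg, hits, gen$assembly,
                                      seed = 10000 + r)
            win <- makeWindows(bp, 100, gen$assembly)
            res <- suppressWarnings(permTest(win, hits, gen$assembly,
                                             nPerm = 100, seed = 20000 + r))
            pValue(res) < 0.05
        }, logical(1))
    })
    expect_lte(mean(reject), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("local z equals the parent at zero shift and needs a defined parent", {
    asm <- GenomeAssembly(c(chr1 = 1000000L))
    centers <- seq(50000, 950000, by = 100000)
    win <- makeWindows(bp0("chr1", centers, asm), 100, asm)
    hits <- gr0("chr1", centers - 6, centers + 7, asm)  # 13 bp at each center
    parent <- permTest(win, hits, asm, nPerm = 200, seed = 4)
    prof <- localZScore(parent, win, hits, asm, maxShift = 500, step = 50)
    expect_identical(prof@z[prof@shifts == 0], zScore(parent))
    expect_error(localZScore(parent, win, hits, asm, maxShift = 500,
                             step = 300), "multiple")

    none <- GenomicRanges::GRanges(seqinfo = seqinfo(asm))
    bad <- suppressWarnings(permTest(win, none, asm, nPerm = 20, seed = 1))
    expect_error(localZScore(bad, win, none, asm), "undefined")
})

test_that("displacement by at least a window width drops the planted signal", {
    asm <- GenomeAssembly(c(chr1 = 2000000L))
    centers <- seq(100000, 1900000, by = 200000)  # isolation >> max shift
    win <- makeWindows(bp0("chr1", centers, asm), 100, asm)
    hits <- gr0("chr1", centers - 6, centers + 7, asm)
    parent <- permTest(win, hits, asm, nPerm = 300, seed = 5)
    prof <- localZScore(parent, win, hits, asm, maxShift = 500, step = 50)
    z0 <- prof@z[prof@shifts == 0]
    away <- abs(prof@shifts) >= 100
    expect_true(all(prof@z[away] < z0))
})
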