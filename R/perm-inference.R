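#' Randomize a region set over the genome
#'
#' Re-places every interval independently and uniformly over all valid
#' starts in the assembly: the chromosome is drawn with probability
#' proportional to `(length - interval length + 1)` (so every genomic start
#' position is equally likely), the start uniformly within it, and
#' placements overlapping the assembly gap mask are rejected and redrawn.
#' Interval lengths are preserved; randomized regions may overlap each
#' other. This is the null model behind [permTest()].
#'
#' @param regions a `GRanges` to re-place.
#' @param assembly a [GenomeAssembly-class].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param perChromosome keep every region on its original chromosome?
#' @return A `GRanges` of the same widths, in input order (metadata dropped).
#' @export
randomizeRegions <- function(regions, assembly, seed = NULL,
                             perChromosome = FALSE) {
    .checkRegions(regions, assembly)
    layout <- .absLayout(assembly)
    widths <- GenomicRanges::width(regions)
    if (max(widths) > .maxFreeRun(layout))
        stop("an interval is longer than every chromosome's largest ",
             "un-masked stretch")
    perChromIdx <- NULL
    if (perChromosome)
        perChromIdx <- match(as.character(GenomicRanges::seqnames(regions)),
                             layout$names)
    pl <- withSeed(seed, .drawPlacements(widths, layout, perChromIdx))
    ci <- findInterval(pl$a, layout$offsets)
    GenomicRanges::GRanges(layout$names[ci],
        IRanges::IRanges(start = pl$a - layout$offsets[ci] + 1,
                         width = widths),
        seqinfo = assembly@seqinfo)
}

.resultShow <- function(object) {
    cat("PermTestResult: observed =", object@observed,
        "of", object@nWindows, "windows;",
        "null", sprintf("%.3f +/- %.3f", object@permMean, object@permSd), "\n")
    cat(sprintf("  z = %s, p = %.4g (alternative = %s, nPerm = %d)\n",
        if (is.na(object@zScore)) "NA (degenerate null)"
        else sprintf("%.3f", object@zScore),
        object@pValue, object@alternative, object@nPerm))
    if (!is.na(object@variantSeq))
        cat("  variant:", object@variantSeq,
            if (!is.na(object@label)) paste0("(", object@label, ")"), "\n")
}
setMethod("show", "PermTestResult", .resultShow)

#' @rdname PermTestResult-class
#' @export
setMethod("observedOverlap", "PermTestResult", function(x) x@observed)

#' @rdname PermTestResult-class
#' @export
setMethod("zScore", "PermTestResult", function(x) x@zScore)

#' @rdname PermTestResult-class
#' @export
setMethod("pValue", "PermTestResult", function(x) x@pValue)

#' @rdname PermTestResult-class
#' @export
setMethod("nullDistribution", "PermTestResult", function(x) x@nullDist)

#' Region-randomization permutation test of motif/window association
#'
#' Tests whether motif occurrences fall inside breakpoint-centered windows
#' more (or less) often than expected if the windows were placed at random.
#' The observed statistic is the count-once overlap
#' `overlapCount(windows, hits)` — the number of windows containing at least
#' one motif occurrence. The null is built by randomizing the window set
#' `nPerm` times over the assembly ([randomizeRegions()]) with the hits held
#' fixed, and recomputing the statistic (set `randomize = "hits"` for the
#' opposite assignment). The empirical p-value uses +1 smoothing,
#' `p = (1 + #{permuted >= observed}) / (nPerm + 1)` (mirrored for
#' `alternative = "less"`), so the smallest attainable p is `1/(nPerm+1)`;
#' with the default `nPerm = 1000` a maximal result prints as p = 0.001.
#' `alternative = "auto"` resolves to `"greater"` when the observed count is
#' at least the null mean, else `"less"`.
#'
#' A degenerate null (`sd = 0`, e.g. when `hits` is empty) yields an `NA`
#' z-score with a warning; the p-value remains valid.
#'
#' @param windows a non-empty `GRanges` of breakpoint windows.
#' @param hits a `GRanges` of motif occurrences (may be empty).
#' @param assembly a [GenomeAssembly-class].
#' @param nPerm number of permutations (>= 1); default 1000.
#' @param seed optional integer seed making the test fully reproducible.
#' @param alternative `"auto"` (default), `"greater"` or `"less"`.
#' @param randomize which set the null re-places: `"windows"` (default) or
#'   `"hits"`.
#' @param perChromosome restrict randomization to the original chromosome?
#' @return A [PermTestResult-class].
#' @examples
#' asm <- GenomeAssembly(c(chr1 = 10000L))
#' win <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(101, 5001), width = 100))
#' hit <- GenomicRanges::GRanges("chr1", IRanges::IRanges(120, width = 13))
#' permTest(win, hit, asm, nPerm = 100, seed = 1)
#' @export
permTest <- function(windows, hits, assembly, nPerm = 1000, seed = NULL,
                     alternative = c("auto", "greater", "less"),
                     randomize = c("windows", "hits"),
                     perChromosome = FALSE) {
    alternative <- match.arg(alternative)
    randomize <- match.arg(randomize)
    if (length(windows) == 0L)
        stop("window set is empty")
    if (nPerm < 1L)
        stop("nPerm must be >= 1")
    .checkRegions(windows, assembly, "window set")
    .checkRegions(hits, assembly, "hit set")
    observed <- overlapCount(windows, hits, countOnce = TRUE)
    layout <- .absLayout(assembly)
    nullDist <- withSeed(seed, {
        if (randomize == "windows") {
            habs <- .toAbs(hits, layout)
            merged <- .mergeAbs(habs$a, habs$b)
            perChromIdx <- if (perChromosome)
                match(as.character(GenomicRanges::seqnames(windows)),
                      layout$names) else NULL
            .permNullCounts(GenomicRanges::width(windows), layout,
                            merged$s, merged$e, nPerm, perChromIdx)
        } else {
            vapply(seq_len(nPerm), function(i) {
                rh <- randomizeRegions(hits, assembly,
                                       perChromosome = perChromosome)
                overlapCount(windows, rh, countOnce = TRUE)
            }, numeric(1))
        }
    })
    permMean <- mean(nullDist)
    permSd <- stats::sd(nullDist)
    if (nPerm == 1L)
        permSd <- 0
    if (alternative == "auto")
        alternative <- if (observed >= permMean) "greater" else "less"
    pValue <- if (alternative == "greater")
        (1 + sum(nullDist >= observed)) / (nPerm + 1)
    else
        (1 + sum(nullDist <= observed)) / (nPerm + 1)
    z <- NA_real_
    if (permSd > 0) {
        z <- (observed - permMean) / permSd
    } else {
        warning("degenerate permutation null (sd = 0); z-score undefined")
    }
    methods::new("PermTestResult",
        observed = as.integer(observed),
        permMean = permMean, permSd = permSd,
        zScore = z, pValue = pValue,
        alternative = alternative,
        nPerm = as.integer(nPerm),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        nWindows = length(windows), nHits = length(hits),
        nullDist = nullDist,
        label = NA_character_, variantSeq = NA_character_,
        variantId = NA_integer_,
        windowWidth = as.integer(max(GenomicRanges::width(windows))))
}

#' Local z-score: positional displacement profile
#'
#' Shifts every window by each signed offset `d` in
#' `{-maxShift, ..., -step, 0, step, ..., +maxShift}` (clipping at
#' chromosome bounds), recomputes the observed count-once statistic, and
#' converts it to a z-score using the *parent* test's null mean and sd — the
#' null is not re-simulated, so the profile is deterministic given the
#' parent. The value at shift 0 equals the parent z-score exactly. A peak at
#' 0 that decays for larger shifts shows the association is tied to the
#' exact breakpoint position.
#'
#' @param parent a [PermTestResult-class] with a defined z-score.
#' @param windows,hits,assembly the inputs of the parent test.
#' @param maxShift largest displacement in bp; default 5x the window width.
#' @param step grid step in bp (must divide `maxShift`); default half the
#'   window width.
#' @return A [LocalZProfile-class].
#' @export
localZScore <- function(parent, windows, hits, assembly,
                        maxShift = NULL, step = NULL) {
    if (is.na(parent@zScore))
        stop("parent result has an undefined z-score (degenerate null)")
    w <- parent@windowWidth
    if (is.null(maxShift)) maxShift <- 5L * w
    if (is.null(step)) step <- max(1L, w %/% 2L)
    if (maxShift %% step != 0)
        stop("maxShift must be a multiple of step")
    shifts <- seq(-maxShift, maxShift, by = step)
    layout <- .absLayout(assembly)
    sn <- as.character(GenomicRanges::seqnames(windows))
    len <- chromLengths(assembly)[sn]
    habs <- .toAbs(hits, layout)
    merged <- .mergeAbs(habs$a, habs$b)
    ci <- match(sn, layout$names)
    z <- vapply(shifts, function(d) {
        s <- pmax(GenomicRanges::start(windows) + d, 1L)
        e <- pmin(GenomicRanges::end(windows) + d, len)
        keep <- s <= e
        a <- layout$offsets[ci[keep]] + s[keep] - 1
        b <- layout$offsets[ci[keep]] + e[keep]
        obs <- sum(.overlapsAny(a, b, merged$s, merged$e))
        (obs - parent@permMean) / parent@permSd
    }, numeric(1))
    methods::new("LocalZProfile", shifts = as.numeric(shifts), z = z,
                 parent = parent)
}

setMethod("show", "LocalZProfile", function(object) {
    cat("LocalZProfile over", length(object@shifts), "shifts in [",
        min(object@shifts), ",", max(object@shifts), "] bp\n")
    cat(sprintf("  z(0) = %.3f; z(+/-max) = %.3f / %.3f\n",
        object@z[object@shifts == 0],
        object@z[which.min(object@shifts)],
        object@z[which.max(object@shifts)]))
})

#' @describeIn localZScore profile as a two-column data.frame
#'   (`shift_bp`, `z`).
#' @param x a `LocalZProfile`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "LocalZProfile", function(x, ...) {
    data.frame(shift_bp = x@shifts, z = x@z)
})
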