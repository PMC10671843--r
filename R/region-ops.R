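#' Breakpoint-centered windows
#'
#' For each breakpoint position `p` (0-based), builds the flanking frame
#' `[p - width/2, p + width/2)` — a window of `width` bp with the breakpoint
#' at its center — clipped to the chromosome. Windows are never merged, even
#' when breakpoints lie closer together than the width: each breakpoint
#' contributes exactly one region, and duplicates are permitted.
#'
#' @param breakpoints a `GRanges` of width-1 breakpoint positions (see
#'   [breakpointPositions()]).
#' @param width total window width in bp; must be even and >= 2.
#' @param assembly the [GenomeAssembly-class] providing chromosome bounds.
#' @return A `GRanges` of windows, in breakpoint order, with a
#'   `breakpoint` metadata column recording the source position (1-based).
#' @examples
#' asm <- GenomeAssembly(c(chr1 = 1000L))
#' bp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, width = 1))
#' makeWindows(bp, 100, asm)  # [450, 550) in 0-based terms
#' @export
makeWindows <- function(breakpoints, width, assembly) {
    if (length(width) != 1L || width < 2 || width %% 2 != 0)
        stop("window width must be a single even integer >= 2")
    if (any(GenomicRanges::width(breakpoints) != 1L))
        stop("breakpoints must be width-1 positions; see breakpointPositions()")
    .checkRegions(breakpoints, assembly, "breakpoint set")
    half <- width %/% 2
    sn <- as.character(GenomicRanges::seqnames(breakpoints))
    len <- chromLengths(assembly)[sn]
    p0 <- GenomicRanges::start(breakpoints) - 1L  # 0-based position
    s0 <- pmax(p0 - half, 0L)
    e0 <- pmin(p0 + half, len)
    out <- GenomicRanges::GRanges(sn,
        IRanges::IRanges(start = s0 + 1L, end = e0),
        seqinfo = assembly@seqinfo)
    S4Vectors::mcols(out)$breakpoint <- p0 + 1L
    out
}

#' Count overlaps between two region sets
#'
#' The overlap statistic of the pipeline. With `countOnce = TRUE` (default)
#' it is the number of `A` intervals sharing at least 1 bp with any `B`
#' interval — each `A` interval counted at most once, so the statistic is
#' robust to stacks of overlapping motif hits. With `countOnce = FALSE` it is
#' the number of overlapping (A, B) pairs. Touching half-open intervals do
#' not overlap.
#'
#' @param A,B `GRanges` on the same assembly.
#' @param countOnce count each `A` interval at most once?
#' @return integer count.
#' @export
overlapCount <- function(A, B, countOnce = TRUE) {
    if (!.sameAssembly(A, B))
        stop("region sets refer to different assemblies")
    n <- GenomicRanges::countOverlaps(A, B, ignore.strand = TRUE)
    if (countOnce) sum(n > 0L) else sum(n)
}

#' List all overlapping pairs with intersection widths
#'
#' @param A,B `GRanges` on the same assembly.
#' @return data.frame with one row per overlapping (A, B) pair: columns
#'   `a_chrom`, `a_start`, `a_end`, `b_chrom`, `b_start`, `b_end` (0-based
#'   half-open, BED convention) and `intersection_bp` (always >= 1).
#' @export
overlapPairs <- function(A, B) {
    if (!.sameAssembly(A, B))
        stop("region sets refer to different assemblies")
    h <- GenomicRanges::findOverlaps(A, B, ignore.strand = TRUE)
    a <- A[S4Vectors::queryHits(h)]
    b <- B[S4Vectors::subjectHits(h)]
    inter <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
             pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
    data.frame(
        a_chrom = as.character(GenomicRanges::seqnames(a)),
        a_start = GenomicRanges::start(a) - 1L,
        a_end = GenomicRanges::end(a),
        b_chrom = as.character(GenomicRanges::seqnames(b)),
        b_start = GenomicRanges::start(b) - 1L,
        b_end = GenomicRanges::end(b),
        intersection_bp = inter,
        stringsAsFactors = FALSE)
}

#' Distance from each window to its nearest feature start
#'
#' Annotates each window with the nearest feature (e.g. a transcription
#' start site) on the same chromosome. Distance is
#' `|window midpoint - feature start|` in 0-based coordinates, using the
#' feature interval's start as the TSS coordinate (BED convention) and the
#' midpoint `floor((start+end)/2)` for windows. Ties are broken toward the
#' feature with the smaller start; windows on chromosomes without any
#' feature get `NA`.
#'
#' @param windows a `GRanges` of windows.
#' @param features a non-empty `GRanges` of features.
#' @return data.frame with columns `chrom`, `window_start`, `window_end`
#'   (0-based half-open), `midpoint`, `feature_start` and `distance`
#'   (`NA` where no same-chromosome feature exists).
#' @export
annotateNearestFeature <- function(windows, features) {
    if (length(features) == 0L)
        stop("feature set is empty")
    if (!.sameAssembly(windows, features))
        stop("region sets refer to different assemblies")
    wchrom <- as.character(GenomicRanges::seqnames(windows))
    mid <- floor((GenomicRanges::start(windows) - 1L +
                  GenomicRanges::end(windows)) / 2)
    fchrom <- as.character(GenomicRanges::seqnames(features))
    fstart <- GenomicRanges::start(features) - 1L
    near <- rep(NA_integer_, length(windows))
    for (chr in unique(wchrom)) {
        f <- sort(unique(fstart[fchrom == chr]))
        if (length(f) == 0L)
            next
        idx <- which(wchrom == chr)
        i <- findInterval(mid[idx], f)
        left <- ifelse(i >= 1L, f[pmax(i, 1L)], NA_integer_)
        right <- ifelse(i < length(f), f[pmin(i + 1L, length(f))], NA_integer_)
        dl <- abs(mid[idx] - left)
        dr <- abs(mid[idx] - right)
        # on a tie the left candidate (smaller start) wins
        near[idx] <- ifelse(is.na(dl), right,
                     ifelse(is.na(dr), left,
                     ifelse(dl <= dr, left, right)))
    }
    data.frame(
        chrom = wchrom,
        window_start = GenomicRanges::start(windows) - 1L,
        window_end = GenomicRanges::end(windows),
        midpoint = mid,
        feature_start = near,
        distance = abs(mid - near),
        stringsAsFactors = FALSE)
}
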