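# Internal fast machinery for the permutation null.
#
# All chromosomes are laid end-to-end on one absolute 0-based half-open axis
# (regions never span chromosome boundaries, so disjoint offsets make
# cross-chromosome false overlaps impossible). Overlap queries against a
# merged, sorted interval list then reduce to two findInterval() calls, and
# a full permutation round randomizes every placement of every permutation
# in one vectorized draw.

.absLayout <- function(assembly) {
    len <- as.numeric(chromLengths(assembly))
    offsets <- c(0, cumsum(len))[seq_along(len)]
    gaps <- gapMask(assembly)
    gs <- ge <- numeric(0)
    if (length(gaps) > 0L) {
        idx <- match(as.character(GenomicRanges::seqnames(gaps)),
                     chromNames(assembly))
        gs <- offsets[idx] + GenomicRanges::start(gaps) - 1
        ge <- offsets[idx] + GenomicRanges::end(gaps)
        o <- order(gs)
        gs <- gs[o]; ge <- ge[o]
    }
    list(lengths = len, offsets = offsets,
         names = chromNames(assembly), gapStart = gs, gapEnd = ge)
}

# GRanges -> absolute half-open [a, b)
.toAbs <- function(gr, layout) {
    idx <- match(as.character(GenomicRanges::seqnames(gr)), layout$names)
    a <- layout$offsets[idx] + GenomicRanges::start(gr) - 1
    list(a = a, b = a + GenomicRanges::width(gr))
}

# merged sorted absolute intervals
.mergeAbs <- function(a, b) {
    if (length(a) == 0L)
        return(list(s = numeric(0), e = numeric(0)))
    o <- order(a)
    a <- a[o]; b <- cummax(b[o])
    new_run <- c(TRUE, a[-1] > b[-length(b)])
    grp <- cumsum(new_run)
    list(s = a[new_run], e = as.numeric(tapply(b, grp, max)))
}

# does [a, b) intersect any merged interval [s_i, e_i)?
.overlapsAny <- function(a, b, s, e) {
    if (length(s) == 0L)
        return(rep(FALSE, length(a)))
    i <- findInterval(a, s)
    hit <- i >= 1L & e[pmax(i, 1L)] > a
    hit | (i < length(s) & s[pmin(i + 1L, length(s))] < b)
}

# Longest un-masked stretch per chromosome (bp); bounds feasible placements.
.maxFreeRun <- function(layout) {
    if (length(layout$gapStart) == 0L)
        return(max(layout$lengths))
    best <- 0
    for (ci in seq_along(layout$lengths)) {
        lo <- layout$offsets[ci]
        hi <- lo + layout$lengths[ci]
        in_chr <- which(layout$gapStart < hi & layout$gapEnd > lo)
        gs <- pmax(layout$gapStart[in_chr], lo)
        ge <- pmin(layout$gapEnd[in_chr], hi)
        o <- order(gs)
        # gap mask is non-overlapping, so free runs interleave the gaps:
        # [lo, gap1), [end1, gap2), ..., [endk, hi)
        starts <- c(lo, ge[o])
        ends <- c(gs[o], hi)
        best <- max(best, max(ends - starts))
    }
    best
}

# Draw absolute placements for `widths`, independently and uniformly over
# all valid starts, chromosome chosen with probability proportional to
# (length - width + 1); placements overlapping the gap mask are redrawn.
# Returns list(a, b) of absolute half-open intervals, in input order.
.drawPlacements <- function(widths, layout, perChromIdx = NULL) {
    n <- length(widths)
    a <- numeric(n)
    for (w in unique(widths)) {
        sel <- which(widths == w)
        if (is.null(perChromIdx)) {
            nvalid <- pmax(layout$lengths - w + 1, 0)
            if (all(nvalid == 0))
                stop("interval of length ", w,
                     " does not fit on any chromosome")
            ci <- sample.int(length(nvalid), length(sel), replace = TRUE,
                             prob = nvalid)
        } else {
            ci <- perChromIdx[sel]
            if (any(layout$lengths[ci] < w))
                stop("interval of length ", w,
                     " does not fit on its chromosome")
        }
        start0 <- floor(stats::runif(length(sel)) *
                        (layout$lengths[ci] - w + 1))
        a[sel] <- layout$offsets[ci] + start0
    }
    b <- a + widths
    if (length(layout$gapStart) > 0L) {
        if (max(widths) > .maxFreeRun(layout))
            stop("an interval is longer than every chromosome's largest ",
                 "un-masked stretch")
        for (iter in seq_len(10000L)) {
            bad <- which(.overlapsAny(a, b, layout$gapStart, layout$gapEnd))
            if (length(bad) == 0L)
                break
            redo <- .drawPlacementsNoGap(widths[bad], layout,
                        if (is.null(perChromIdx)) NULL else perChromIdx[bad])
            a[bad] <- redo$a
            b[bad] <- redo$b
            if (iter == 10000L)
                stop("could not place regions outside the gap mask")
        }
    }
    list(a = a, b = b)
}

# one raw draw without gap rejection (used by the rejection loop)
.drawPlacementsNoGap <- function(widths, layout, perChromIdx) {
    n <- length(widths)
    a <- numeric(n)
    for (w in unique(widths)) {
        sel <- which(widths == w)
        if (is.null(perChromIdx)) {
            nvalid <- pmax(layout$lengths - w + 1, 0)
            ci <- sample.int(length(nvalid), length(sel), replace = TRUE,
                             prob = nvalid)
        } else {
            ci <- perChromIdx[sel]
        }
        start0 <- floor(stats::runif(length(sel)) *
                        (layout$lengths[ci] - w + 1))
        a[sel] <- layout$offsets[ci] + start0
    }
    list(a = a, b = a + widths)
}

# Permutation null for the count-once statistic with the query set
# randomized: all nPerm x nRegions placements drawn at once.
.permNullCounts <- function(widths, layout, subjS, subjE, nPerm,
                            perChromIdx = NULL) {
    W <- length(widths)
    allW <- rep(widths, times = nPerm)
    allC <- if (is.null(perChromIdx)) NULL else rep(perChromIdx, times = nPerm)
    pl <- .drawPlacements(allW, layout, allC)
    ov <- .overlapsAny(pl$a, pl$b, subjS, subjE)
    permId <- rep(seq_len(nPerm), each = W)
    as.numeric(tabulate(permId[ov], nbins = nPerm))
}
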