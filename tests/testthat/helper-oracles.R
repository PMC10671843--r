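# Independent oracles and tiny fixture builders. These deliberately avoid
# the package's own scanning/overlap code paths.

# IUPAC base sets, duplicated here so the oracle does not share a table with
# the implementation under test.
ORACLE_IUPAC <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# naive O(L*m) sliding-window scan; returns 0-based start positions.
# N in the subject never matches (masked positions).
bruteScan <- function(seq, pattern) {
    sch <- strsplit(seq, "")[[1]]
    pch <- strsplit(pattern, "")[[1]]
    m <- length(pch)
    starts <- integer(0)
    if (length(sch) < m) return(starts)
    for (s in 0:(length(sch) - m)) {
        ok <- TRUE
        for (j in seq_len(m)) {
            base <- sch[s + j]
            if (!(base %in% ORACLE_IUPAC[[pch[j]]])) { ok <- FALSE; break }
        }
        if (ok) starts <- c(starts, s)
    }
    starts
}

# all-pairs O(|A|*|B|) overlap oracle on GRanges (1 bp minimum intersection,
# half-open discipline honoured by the closed-coordinate equivalent).
bruteOverlap <- function(A, B) {
    ac <- as.character(GenomicRanges::seqnames(A))
    bc <- as.character(GenomicRanges::seqnames(B))
    as_ <- GenomicRanges::start(A); ae <- GenomicRanges::end(A)
    bs <- GenomicRanges::start(B); be <- GenomicRanges::end(B)
    pairs <- 0L
    touched <- logical(length(A))
    for (i in seq_along(A)) {
        for (j in seq_along(B)) {
            if (ac[i] == bc[j] && as_[i] <= be[j] && bs[j] <= ae[i]) {
                pairs <- pairs + 1L
                touched[i] <- TRUE
            }
        }
    }
    list(countOnce = sum(touched), pairs = pairs)
}

# random region set on an assembly, widths in [1, maxw]
randomRegionSet <- function(assembly, n, maxw = 50L) {
    len <- chromLengths(assembly)
    ci <- sample.int(length(len), n, replace = TRUE)
    w <- sample.int(maxw, n, replace = TRUE)
    w <- pmin(w, len[ci])
    s <- floor(runif(n) * (len[ci] - w + 1)) + 1L
    GenomicRanges::GRanges(names(len)[ci], IRanges::IRanges(s, width = w),
                           seqinfo = seqinfo(assembly))
}

# random A/C/G/T string
randomSeq <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# GRanges from 0-based half-open triples, for readable expected values
gr0 <- function(chrom, start0, end0, assembly = NULL) {
    if (is.null(assembly))
        return(GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = start0 + 1L, end = end0)))
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1L, end = end0),
        seqinfo = seqinfo(assembly))
}

# width-1 breakpoint GRanges at 0-based positions
bp0 <- function(chrom, pos0, assembly) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, width = 1L),
                           seqinfo = seqinfo(assembly))
}

writeTempFasta <- function(records, wrap = NULL) {
    path <- tempfile(fileext = ".fa")
    lines <- character(0)
    for (nm in names(records)) {
        seq <- records[[nm]]
        if (!is.null(wrap)) {
            starts <- seq(1, nchar(seq), by = wrap)
            seq <- vapply(starts, function(s)
                substr(seq, s, min(s + wrap - 1, nchar(seq))), character(1))
        }
        lines <- c(lines, paste0(">", nm), seq)
    }
    writeLines(lines, path)
    path
}
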