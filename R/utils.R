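# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. A NULL seed means "use the current stream".
withSeed <- function(seed, code) {
    if (is.null(seed))
        return(force(code))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    force(code)
}

# Stable 31-bit hash of (baseSeed, ...parts), used to derive per-combination
# seeds so any single screen combination can be re-run in isolation and match
# the full screen. Arithmetic stays below 2^53 so doubles are exact.
comboSeed <- function(baseSeed, ...) {
    key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
    h <- as.numeric(baseSeed) %% 2147483647
    for (code in utf8ToInt(key))
        h <- (h * 31 + code) %% 2147483647
    as.integer(h)
}

# Maximal N-runs of a DNAStringSet as a sorted GRanges on `si`.
.nRunRanges <- function(dss, si) {
    hits <- Biostrings::vmatchPattern("N", dss, fixed = TRUE)
    nm <- GenomeInfoDb::seqnames(si)
    parts <- lapply(seq_along(dss), function(i) {
        ir <- IRanges::reduce(hits[[i]])
        if (length(ir) == 0L)
            return(GenomicRanges::GRanges(seqinfo = si))
        GenomicRanges::GRanges(nm[i], ir, seqinfo = si)
    })
    GenomicRanges::sort(do.call(c, parts), ignore.strand = TRUE)
}

# Validate that a GRanges is resolvable against an assembly: known
# chromosomes and ends within bounds. `what` names the offender in errors.
.checkRegions <- function(gr, assembly, what = "region set") {
    sn <- as.character(GenomicRanges::seqnames(gr))
    known <- as.character(chromNames(assembly))
    bad <- setdiff(unique(sn), known)
    if (length(bad))
        stop(what, " refers to unknown chromosome(s): ",
             paste(bad, collapse = ", "))
    len <- chromLengths(assembly)[sn]
    if (any(GenomicRanges::end(gr) > len) || any(GenomicRanges::start(gr) < 1L))
        stop(what, " has interval(s) outside chromosome bounds")
    invisible(TRUE)
}

# Coerce a GRanges onto the assembly's seqinfo (chromosome order) and sort.
.onAssembly <- function(gr, assembly) {
    .checkRegions(gr, assembly)
    GenomeInfoDb::seqlevels(gr) <- as.character(chromNames(assembly))
    GenomeInfoDb::seqinfo(gr) <- assembly@seqinfo
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

.sameAssembly <- function(a, b) {
    identical(as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(a))),
              as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(b)))) &&
    identical(unname(GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(a))),
              unname(GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(b))))
}
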