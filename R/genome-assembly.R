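#' Construct a sequence-free GenomeAssembly
#'
#' Builds the coordinate universe from chromosome names and lengths only, as
#' used by randomization-only workflows driven by a chrom.sizes table.
#'
#' @param lengths named integer vector of chromosome lengths (bp), in the
#'   order the chromosomes should keep throughout the analysis.
#' @return A [GenomeAssembly-class] without sequence.
#' @examples
#' GenomeAssembly(c(chr1 = 1000L, chr2 = 500L))
#' @export
GenomeAssembly <- function(lengths) {
    if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
        stop("chromosome lengths must be named")
    if (any(lengths != as.integer(lengths)))
        stop("chromosome lengths must be integers")
    lengths <- stats::setNames(as.integer(lengths), names(lengths))
    si <- GenomeInfoDb::Seqinfo(seqnames = names(lengths), seqlengths = lengths)
    methods::new("GenomeAssembly",
        seqinfo = si,
        sequence = Biostrings::DNAStringSet(),
        gaps = GenomicRanges::GRanges(seqinfo = si))
}

#' Build a GenomeAssembly from nucleotide sequences
#'
#' Sanitizes the input the way the scanner expects it: sequences are
#' uppercased, `U` is mapped to `T`, and every other character outside
#' `A/C/G/T` — including IUPAC ambiguity codes — is masked to `N` and covered
#' by the gap mask, so a degenerate genome position can never count as a
#' motif match.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet]; one
#'   entry per chromosome, in assembly order.
#' @return A [GenomeAssembly-class] with sequence and gap mask.
#' @examples
#' assemblyFromSequences(c(chr1 = "acgtRN"))  # stored as "ACGTNN"
#' @export
assemblyFromSequences <- function(seqs) {
    if (methods::is(seqs, "XStringSet"))
        seqs <- as.character(seqs)
    if (length(seqs) == 0L)
        stop("no sequences given")
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("sequences must be named by chromosome")
    if (anyDuplicated(names(seqs)))
        stop("duplicate chromosome name(s): ",
             paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
    zero <- nchar(seqs) == 0L
    if (any(zero))
        stop("zero-length record(s): ", paste(names(seqs)[zero], collapse = ", "))
    clean <- toupper(seqs)
    clean <- chartr("U", "T", clean)
    clean <- gsub("[^ACGT]", "N", clean)
    dss <- Biostrings::DNAStringSet(clean)
    names(dss) <- names(seqs)
    si <- GenomeInfoDb::Seqinfo(seqnames = names(seqs),
                                seqlengths = Biostrings::width(dss))
    methods::new("GenomeAssembly",
        seqinfo = si,
        sequence = dss,
        gaps = .nRunRanges(dss, si))
}

#' @rdname GenomeAssembly-class
#' @export
setMethod("chromNames", "GenomeAssembly", function(x)
    as.character(GenomeInfoDb::seqnames(x@seqinfo)))

#' @rdname GenomeAssembly-class
#' @export
setMethod("chromLengths", "GenomeAssembly", function(x) {
    len <- GenomeInfoDb::seqlengths(x@seqinfo)
    stats::setNames(as.integer(len), names(len))
})

#' @rdname GenomeAssembly-class
#' @export
setMethod("hasSequence", "GenomeAssembly", function(x)
    length(x@sequence) > 0L)

#' @rdname GenomeAssembly-class
#' @export
setMethod("genomeSequence", "GenomeAssembly", function(x) {
    if (!hasSequence(x))
        stop("assembly carries no sequence")
    x@sequence
})

#' @rdname GenomeAssembly-class
#' @export
setMethod("gapMask", "GenomeAssembly", function(x) x@gaps)

setMethod("show", "GenomeAssembly", function(object) {
    n <- length(chromNames(object))
    cat("GenomeAssembly with", n, "chromosome(s),",
        format(sum(as.numeric(chromLengths(object))), big.mark = ","), "bp total;",
        if (hasSequence(object)) "with sequence" else "sequence-free", "\n")
    if (length(object@gaps))
        cat("  gap mask:", length(object@gaps), "interval(s),",
            sum(GenomicRanges::width(object@gaps)), "bp masked\n")
    show <- utils::head(chromNames(object), 5L)
    cat("  ", paste(sprintf("%s (%d bp)", show, chromLengths(object)[show]),
                    collapse = ", "),
        if (n > 5L) ", ..." else "", "\n", sep = "")
})

#' Seqinfo of a GenomeAssembly
#' @param x a `GenomeAssembly`.
#' @return the assembly's [GenomeInfoDb::Seqinfo].
#' @export
setMethod("seqinfo", "GenomeAssembly", function(x) x@seqinfo)
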