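#' Consensus motif of a set of equal-length sequences
#'
#' Builds the unweighted position x base (A/C/G/T) count matrix over the
#' given sequences — typically the variants flagged significant by a screen
#' — and derives the IUPAC consensus string: at each position, the minimal
#' IUPAC code covering every base observed there. Positions that are
#' invariant across the inputs (e.g. the fixed positions of the parent
#' degenerate motif) reproduce their fixed base; feeding in *all* expansions
#' of a degenerate motif reproduces the degenerate pattern itself.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet] of
#'   equal-length A/C/G/T sequences.
#' @return A [ConsensusMotif-class].
#' @examples
#' consensusString(consensusMotif(c("CAT", "CCT")))  # "CMT"
#' @export
consensusMotif <- function(sequences) {
    seqs <- as.character(sequences)
    if (length(seqs) == 0L)
        stop("no sequences given")
    if (length(unique(nchar(seqs))) != 1L)
        stop("sequences have mixed lengths")
    if (any(grepl("[^ACGT]", toupper(seqs))))
        stop("sequences must be concrete (A/C/G/T only)")
    dss <- Biostrings::DNAStringSet(toupper(seqs))
    cm <- Biostrings::consensusMatrix(dss)
    counts <- matrix(0L, nrow = 4L, ncol = nchar(seqs[1L]),
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    present <- intersect(rownames(cm), rownames(counts))
    counts[present, ] <- cm[present, , drop = FALSE]
    consensus <- paste(vapply(seq_len(ncol(counts)), function(j) {
        bases <- rownames(counts)[counts[, j] > 0L]
        Biostrings::mergeIUPACLetters(paste(bases, collapse = ""))
    }, character(1)), collapse = "")
    methods::new("ConsensusMotif",
        counts = counts,
        consensus = consensus,
        nSequences = length(seqs))
}

#' @describeIn ConsensusMotif-class the IUPAC consensus string.
#' @param x a `ConsensusMotif`.
#' @export
setMethod("consensusString", "ConsensusMotif", function(x) x@consensus)

#' @describeIn ConsensusMotif-class the 4 x L position count matrix.
#' @export
setMethod("consensusMatrix", "ConsensusMotif",
    function(x, as.prob = FALSE, shift = 0L, width = NULL, ...) {
        if (as.prob)
            return(sweep(x@counts, 2L, colSums(x@counts), "/"))
        x@counts
    })

setMethod("show", "ConsensusMotif", function(object) {
    cat("ConsensusMotif over", object@nSequences, "sequence(s):",
        object@consensus, "\n")
})
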