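#' @import methods
#' @importFrom stats median p.adjust pnorm quantile runif sd setNames
#' @importFrom utils read.table write.table
#' @importFrom GenomeInfoDb seqinfo
#' @importFrom Biostrings consensusString consensusMatrix
#' @importClassesFrom GenomeInfoDb Seqinfo
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom BiocGenerics start end width
NULL

#' GenomeAssembly: chromosomes, optional sequence, and assembly gaps
#'
#' A `GenomeAssembly` is the coordinate universe for the whole pipeline: an
#' ordered set of chromosomes with declared lengths, optionally carrying the
#' actual nucleotide sequence (uppercase over A/C/G/T/N), and a gap mask
#' covering every run of `N` in that sequence. The gap mask is what the
#' region-randomization null respects: a randomized region is never placed
#' across a masked (assembly-gap or ambiguous) position, and a motif match is
#' never reported across one.
#'
#' Chromosome order is the input order (FASTA record order or chrom.sizes row
#' order), not lexicographic; all sorting of regions respects it.
#'
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] holding chromosome names and
#'   lengths, in input order.
#' @slot sequence A [Biostrings::DNAStringSet] with one entry per chromosome,
#'   or a zero-length set when the assembly is sequence-free (chrom.sizes
#'   workflows).
#' @slot gaps A [GenomicRanges::GRanges] covering exactly the maximal runs of
#'   `N` in `sequence` (empty when sequence-free).
#'
#' @seealso [assemblyFromSequences()], [readGenomeFasta()], [readChromSizes()]
#' @exportClass GenomeAssembly
setClass("GenomeAssembly",
    representation(
        seqinfo = "Seqinfo",
        sequence = "DNAStringSet",
        gaps = "GRanges"
    )
)

.validGenomeAssembly <- function(object) {
    msgs <- character(0)
    si <- object@seqinfo
    nm <- GenomeInfoDb::seqnames(si)
    len <- GenomeInfoDb::seqlengths(si)
    if (length(nm) == 0L)
        msgs <- c(msgs, "assembly has no chromosomes")
    if (anyDuplicated(nm))
        msgs <- c(msgs, "duplicated chromosome names")
    if (any(is.na(len)) || any(len < 1L))
        msgs <- c(msgs, "every chromosome length must be a known positive integer")
    if (length(object@sequence) > 0L) {
        if (!identical(names(object@sequence), as.character(nm)))
            msgs <- c(msgs, "sequence names must equal chromosome names, in order")
        else if (!identical(unname(Biostrings::width(object@sequence)),
                            unname(as.integer(len))))
            msgs <- c(msgs, "sequence widths must equal declared chromosome lengths")
        bad <- Biostrings::letterFrequency(object@sequence, "ACGTN")
        if (any(rowSums(bad) != Biostrings::width(object@sequence)))
            msgs <- c(msgs, "sequence may only contain A, C, G, T, N")
        expected <- .nRunRanges(object@sequence, si)
        got <- GenomicRanges::sort(object@gaps, ignore.strand = TRUE)
        if (!identical(as.character(GenomicRanges::seqnames(expected)),
                       as.character(GenomicRanges::seqnames(got))) ||
            !identical(GenomicRanges::start(expected), GenomicRanges::start(got)) ||
            !identical(GenomicRanges::end(expected), GenomicRanges::end(got)))
            msgs <- c(msgs, "gap mask must cover exactly the maximal N-runs of the sequence")
    } else if (length(object@gaps) > 0L) {
        msgs <- c(msgs, "sequence-free assembly cannot carry a gap mask")
    }
    if (length(msgs)) msgs else TRUE
}
setValidity("GenomeAssembly", .validGenomeAssembly)

#' PermTestResult: one region-randomization permutation test
#'
#' Holds the observed overlap statistic, the permutation null (its full
#' distribution plus mean/sd), the z-score, the +1-smoothed empirical
#' p-value, and full provenance (seed, number of permutations, resolved
#' alternative) for one (motif variant, breakpoint set, window width)
#' combination. The statistic is, by default, the number of breakpoint
#' windows containing at least one motif occurrence ("count-once").
#'
#' The p-value is `(1 + #{permuted at least as extreme}) / (nPerm + 1)`, so
#' its floor is `1/(nPerm+1)`; the z-score is
#' `(observed - mean(null)) / sd(null)`, reported as `NA` (with a warning at
#' construction) when the null is degenerate (`sd = 0`).
#'
#' @slot observed integer; observed overlap statistic.
#' @slot permMean,permSd numeric; mean and sd of the permutation null.
#' @slot zScore numeric; `NA` when `permSd == 0`.
#' @slot pValue numeric in (0, 1].
#' @slot alternative `"greater"` or `"less"` (the resolved side).
#' @slot nPerm,seed integers; permutation count and RNG seed (seed may be NA).
#' @slot nWindows,nHits integers; sizes of the two region sets.
#' @slot nullDist numeric vector of length `nPerm`, the permuted statistics.
#' @slot label,variantSeq character; breakpoint-set label and variant
#'   sequence (may be NA when unused).
#' @slot variantId,windowWidth integer; variant index and window width
#'   (may be NA when unused).
#'
#' @seealso [permTest()], [localZScore()], [screenAll()]
#' @exportClass PermTestResult
setClass("PermTestResult",
    representation(
        observed = "integer",
        permMean = "numeric",
        permSd = "numeric",
        zScore = "numeric",
        pValue = "numeric",
        alternative = "character",
        nPerm = "integer",
        seed = "integer",
        nWindows = "integer",
        nHits = "integer",
        nullDist = "numeric",
        label = "character",
        variantSeq = "character",
        variantId = "integer",
        windowWidth = "integer"
    )
)

setValidity("PermTestResult", function(object) {
    msgs <- character(0)
    if (object@nPerm < 1L)
        msgs <- c(msgs, "nPerm must be >= 1")
    if (length(object@nullDist) != object@nPerm)
        msgs <- c(msgs, "nullDist length must equal nPerm")
    if (!(object@alternative %in% c("greater", "less")))
        msgs <- c(msgs, "alternative must be resolved to 'greater' or 'less'")
    if (object@pValue <= 0 || object@pValue > 1)
        msgs <- c(msgs, "pValue must lie in (0, 1]")
    if (object@pValue < 1 / (object@nPerm + 1) - 1e-12)
        msgs <- c(msgs, "pValue below the 1/(nPerm+1) floor")
    if (length(msgs)) msgs else TRUE
})

#' LocalZProfile: z-scores of positionally displaced windows
#'
#' The displacement control for a [PermTestResult]: each window is shifted by
#' a signed offset (clipping at chromosome ends), the overlap statistic is
#' recomputed, and converted to a z-score using the *parent* test's null mean
#' and sd (the null is not re-simulated). A sharp peak at shift 0 indicates
#' that the association is tied to the exact breakpoint position rather than
#' to the broader neighborhood.
#'
#' @slot shifts numeric vector of signed offsets in bp, symmetric around 0.
#' @slot z numeric vector, one z-score per shift; `z` at shift 0 equals the
#'   parent's z-score exactly.
#' @slot parent the [PermTestResult] whose null is reused.
#'
#' @seealso [localZScore()]
#' @exportClass LocalZProfile
setClass("LocalZProfile",
    representation(
        shifts = "numeric",
        z = "numeric",
        parent = "PermTestResult"
    )
)

setValidity("LocalZProfile", function(object) {
    msgs <- character(0)
    if (length(object@shifts) != length(object@z))
        msgs <- c(msgs, "shifts and z must have equal length")
    if (!any(object@shifts == 0))
        msgs <- c(msgs, "shift grid must contain 0")
    if (length(msgs)) msgs else TRUE
})

#' ConsensusMotif: position base counts and IUPAC consensus
#'
#' Per-position A/C/G/T counts over a set of equal-length sequences (e.g. the
#' significant variants from a screen) and the derived IUPAC consensus
#' string: at each position, the minimal IUPAC code covering every base with
#' a nonzero count.
#'
#' @slot counts 4 x L integer matrix with rownames A, C, G, T; every column
#'   sums to the number of contributing sequences.
#' @slot consensus character scalar of length-L IUPAC string.
#' @slot nSequences integer; number of contributing sequences.
#'
#' @seealso [consensusMotif()]
#' @exportClass ConsensusMotif
setClass("ConsensusMotif",
    representation(
        counts = "matrix",
        consensus = "character",
        nSequences = "integer"
    )
)

setValidity("ConsensusMotif", function(object) {
    msgs <- character(0)
    if (!identical(rownames(object@counts), c("A", "C", "G", "T")))
        msgs <- c(msgs, "counts must have rows A, C, G, T")
    if (any(colSums(object@counts) != object@nSequences))
        msgs <- c(msgs, "every column of counts must sum to nSequences")
    if (nchar(object@consensus) != ncol(object@counts))
        msgs <- c(msgs, "consensus length must equal ncol(counts)")
    if (length(msgs)) msgs else TRUE
})
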