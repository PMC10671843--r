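# IUPAC nucleotide codes and the base set each one covers. Kept as the
# single source of truth for expansion, validation and consensus building.
.IUPAC <- c(
    A = "A", C = "C", G = "G", T = "T",
    R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
    B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' The default degenerate recognition motif
#'
#' The 13-bp PRDM9 zinc-finger recognition motif, `CCNCCNTNNCCNC`, with five
#' fully degenerate positions and hence 4^5 = 1024 concrete variants.
#'
#' @export
PRDM9_MOTIF <- "CCNCCNTNNCCNC"

.checkIupac <- function(pattern) {
    if (length(pattern) != 1L || is.na(pattern) || !nzchar(pattern))
        stop("motif pattern must be a non-empty string")
    chars <- strsplit(toupper(pattern), "")[[1L]]
    bad <- which(!(chars %in% names(.IUPAC)))
    if (length(bad))
        stop("invalid IUPAC code '", chars[bad[1L]], "' at position ", bad[1L])
    chars
}

#' Number of concrete variants of a degenerate motif
#'
#' @param pattern IUPAC pattern string.
#' @return product over positions of the size of each position's base set.
#' @examples
#' motifCardinality("CCNCCNTNNCCNC")  # 1024
#' @export
motifCardinality <- function(pattern) {
    chars <- .checkIupac(pattern)
    prod(nchar(.IUPAC[chars]))
}

#' Expand a degenerate IUPAC motif into its concrete variants
#'
#' Enumerates every distinct A/C/G/T string matching the pattern, in
#' lexicographic order (A < C < G < T). The position of a variant in this
#' ordering is its stable `variant_id`, comparable across runs.
#'
#' @param pattern IUPAC pattern string, e.g. `"CCNCCNTNNCCNC"`.
#' @param maxVariants safety cap on the number of expansions.
#' @return A [Biostrings::DNAStringSet] of all variants, named by
#'   `variant_id` (`"1"`, `"2"`, ...).
#' @examples
#' expandDegenerate("ANT")  # AAT, ACT, AGT, ATT
#' length(expandDegenerate("CCNCCNTNNCCNC"))  # 1024
#' @export
expandDegenerate <- function(pattern, maxVariants = 1e6) {
    chars <- .checkIupac(pattern)
    card <- prod(nchar(.IUPAC[chars]))
    if (card > maxVariants)
        stop("pattern expands to ", card, " variants, above maxVariants")
    variants <- ""
    for (ch in chars) {
        bases <- sort(strsplit(.IUPAC[[ch]], "")[[1L]])
        variants <- as.vector(t(outer(variants, bases, paste0)))
    }
    out <- Biostrings::DNAStringSet(variants)
    names(out) <- as.character(seq_along(out))
    out
}

#' Scan a genome for a motif
#'
#' Locates every occurrence of a concrete variant (or of a degenerate IUPAC
#' pattern) in the assembly sequence, one interval per occurrence;
#' occurrences may overlap each other and are never merged. A match is never
#' reported across a masked (`N`) genome position. Under
#' `strandMode = "both"`, reverse-complement matches are reported on the
#' forward coordinate system and deduplicated against identical forward
#' intervals; the default is forward-only.
#'
#' @param assembly a [GenomeAssembly-class] with sequence.
#' @param pattern an A/C/G/T variant string, or a degenerate IUPAC pattern.
#' @param strandMode `"forward"` (default) or `"both"`.
#' @return A sorted `GRanges` of occurrences.
#' @examples
#' asm <- assemblyFromSequences(c(chr1 = "CCACCATCACCACAA"))
#' scanMotif(asm, "CCACCATCACCAC")
#' @export
scanMotif <- function(assembly, pattern, strandMode = c("forward", "both")) {
    strandMode <- match.arg(strandMode)
    chars <- .checkIupac(pattern)
    if (!hasSequence(assembly))
        stop("assembly carries no sequence; scanning needs one")
    pattern <- paste(chars, collapse = "")
    degenerate <- any(nchar(.IUPAC[chars]) > 1L)
    patterns <- pattern
    if (strandMode == "both") {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(pattern)))
        patterns <- unique(c(pattern, rc))
    }
    if (nchar(pattern) > max(chromLengths(assembly))) {
        warning("pattern is longer than every chromosome; no hits possible")
        return(GenomicRanges::GRanges(seqinfo = assembly@seqinfo))
    }
    seqs <- genomeSequence(assembly)
    nm <- chromNames(assembly)
    parts <- list()
    for (i in seq_along(seqs)) {
        if (nchar(pattern) > Biostrings::width(seqs)[i])
            next
        for (p in patterns) {
            m <- Biostrings::matchPattern(p, seqs[[i]],
                fixed = if (degenerate) "subject" else TRUE)
            if (length(m))
                parts[[length(parts) + 1L]] <- GenomicRanges::GRanges(
                    nm[i], IRanges::IRanges(Biostrings::start(m),
                                            Biostrings::end(m)),
                    seqinfo = assembly@seqinfo)
        }
    }
    if (length(parts) == 0L)
        return(GenomicRanges::GRanges(seqinfo = assembly@seqinfo))
    gr <- unique(GenomicRanges::sort(do.call(c, parts), ignore.strand = TRUE))
    if (degenerate && length(gapMask(assembly)) > 0L) {
        # with fixed = "subject" a pattern N would match a masked N; reject
        # any hit touching the gap mask so degenerate positions never count
        hit <- GenomicRanges::countOverlaps(gr, gapMask(assembly)) > 0L
        gr <- gr[!hit]
    }
    gr
}

#' Scan a genome for every variant of a degenerate motif
#'
#' Applies [scanMotif()] to each concrete expansion of the pattern and also
#' returns the union of all per-variant hits, which equals a direct scan
#' with the degenerate pattern itself.
#'
#' @inheritParams scanMotif
#' @param pattern degenerate IUPAC pattern.
#' @return A list with elements
#'   \describe{
#'     \item{variants}{[GenomicRanges::GRangesList] named by `variant_id`;}
#'     \item{union}{`GRanges`, the union of all per-variant hits;}
#'     \item{manifest}{data.frame with columns `variant_id`, `sequence`,
#'       `n_hits`.}
#'   }
#' @export
scanAllVariants <- function(assembly, pattern, strandMode = c("forward", "both")) {
    strandMode <- match.arg(strandMode)
    variants <- expandDegenerate(pattern)
    hits <- lapply(as.character(variants), function(v)
        suppressWarnings(scanMotif(assembly, v, strandMode)))
    names(hits) <- names(variants)
    grl <- GenomicRanges::GRangesList(hits)
    all <- unlist(grl, use.names = FALSE)
    union <- unique(GenomicRanges::sort(all, ignore.strand = TRUE))
    list(
        variants = grl,
        union = union,
        manifest = data.frame(
            variant_id = as.integer(names(variants)),
            sequence = as.character(variants),
            n_hits = lengths(hits),
            row.names = NULL,
            stringsAsFactors = FALSE)
    )
}
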