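#' Read a genome from FASTA
#'
#' Reads a multi-record FASTA (wrapped or unwrapped) into a
#' [GenomeAssembly-class]. Sequences are uppercased, `U` becomes `T`, and any
#' other character outside `A/C/G/T` is masked to `N` and covered by the gap
#' mask. Chromosome order is the file order. Record names are the FASTA
#' header up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return A [GenomeAssembly-class] with sequence.
#' @seealso [assemblyFromSequences()] for the sanitization contract.
#' @export
readGenomeFasta <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    seqs <- tryCatch(Biostrings::readBStringSet(path),
                     error = function(e) stop("invalid FASTA '", path, "': ",
                                              conditionMessage(e)))
    if (length(seqs) == 0L)
        stop("FASTA file '", path, "' contains no records")
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    assemblyFromSequences(stats::setNames(as.character(seqs), names(seqs)))
}

#' Write a genome to FASTA
#'
#' @param assembly a [GenomeAssembly-class] with sequence.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(assembly, path, width = 70L) {
    Biostrings::writeXStringSet(genomeSequence(assembly), path, width = width)
    invisible(path)
}

#' Read a UCSC chrom.sizes table
#'
#' Two tab- or space-separated columns (chromosome name, length in bp) become
#' a sequence-free [GenomeAssembly-class] for randomization-only workflows.
#'
#' @param path path to the two-column table.
#' @return A [GenomeAssembly-class] without sequence.
#' @export
readChromSizes <- function(path) {
    tab <- utils::read.table(path, header = FALSE, sep = "",
                             colClasses = "character",
                             col.names = c("chrom", "length"))
    if (nrow(tab) == 0L)
        stop("empty chrom.sizes file: ", path)
    if (anyDuplicated(tab$chrom))
        stop("duplicate chromosome name(s) in '", path, "': ",
             paste(unique(tab$chrom[duplicated(tab$chrom)]), collapse = ", "))
    len <- suppressWarnings(as.numeric(tab$length))
    bad <- which(is.na(len) | len != floor(len))
    if (length(bad))
        stop("non-integer length at line ", bad[1L], " of '", path, "'")
    if (any(len < 1))
        stop("chromosome length must be >= 1 (line ",
             which(len < 1)[1L], " of '", path, "')")
    GenomeAssembly(stats::setNames(as.integer(len), tab$chrom))
}

#' Read a BED file against an assembly
#'
#' Parses a BED3+ file into a [GenomicRanges::GRanges] validated against the
#' given assembly: every chromosome must exist and every interval must fit
#' within its chromosome. Input is 0-based half-open (BED convention); the
#' returned GRanges is 1-based closed (Bioconductor convention) — the two
#' describe the same base-pair sets and [writeBed()] converts back exactly.
#' Columns beyond the third are preserved as opaque character metadata
#' columns `bed4`, `bed5`, .... Header lines (`track`, `browser`, `#`) are
#' skipped with a warning. Output is sorted by (assembly chromosome order,
#' start, end).
#'
#' @param path path to a BED file.
#' @param assembly the [GenomeAssembly-class] the coordinates refer to.
#' @return A sorted `GRanges` carrying the assembly's seqinfo.
#' @export
readBed <- function(path, assembly) {
    lines <- readLines(path)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
    if (any(!keep & nzchar(lines)))
        warning("skipped ", sum(!keep & nzchar(lines)),
                " header/track line(s) in '", path, "'")
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L) {
        return(GenomicRanges::GRanges(seqinfo = assembly@seqinfo))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("fewer than 3 columns at line ", lineno[which(nf < 3L)[1L]],
             " of '", path, "'")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    badnum <- which(is.na(start0) | is.na(end0) |
                    start0 != floor(start0) | end0 != floor(end0))
    if (length(badnum))
        stop("non-integer coordinates at line ", lineno[badnum[1L]],
             " of '", path, "'")
    known <- chromNames(assembly)
    badchr <- which(!(chrom %in% known))
    if (length(badchr))
        stop("unknown chromosome '", chrom[badchr[1L]], "' at line ",
             lineno[badchr[1L]], " of '", path, "'")
    badord <- which(start0 >= end0)
    if (length(badord))
        stop("start >= end at line ", lineno[badord[1L]], " of '", path, "'")
    if (any(start0 < 0))
        stop("negative start at line ", lineno[which(start0 < 0)[1L]],
             " of '", path, "'")
    len <- chromLengths(assembly)[chrom]
    badlen <- which(end0 > len)
    if (length(badlen))
        stop("end beyond chromosome ", chrom[badlen[1L]], " length (",
             len[badlen[1L]], ") at line ", lineno[badlen[1L]],
             " of '", path, "'")
    gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = start0 + 1L, end = end0),
            seqinfo = assembly@seqinfo)
    extra <- max(nf)
    if (extra > 3L) {
        for (j in seq(4L, extra)) {
            col <- vapply(fields, function(f)
                if (length(f) >= j) f[[j]] else NA_character_, character(1))
            S4Vectors::mcols(gr)[[paste0("bed", j)]] <- col
        }
    }
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write regions to BED
#'
#' Serializes a `GRanges` as sorted, tab-separated, 0-based half-open BED
#' with no header. Metadata columns (in order) are appended after the three
#' coordinate columns, so a [readBed()] round-trip reproduces the input
#' exactly. An empty region set yields an empty file.
#'
#' @param regions a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(regions, path) {
    regions <- GenomicRanges::sort(regions, ignore.strand = TRUE)
    if (length(regions) == 0L) {
        if (!file.create(path))
            stop("cannot write to '", path, "'")
        return(invisible(path))
    }
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(regions)),
        start = GenomicRanges::start(regions) - 1L,
        end = GenomicRanges::end(regions),
        stringsAsFactors = FALSE)
    mc <- S4Vectors::mcols(regions)
    if (ncol(mc) > 0L)
        df <- cbind(df, as.data.frame(mc, stringsAsFactors = FALSE))
    ok <- tryCatch({
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok)
        stop("cannot write to '", path, "'")
    invisible(path)
}

#' Breakpoint positions from BED intervals
#'
#' A breakpoint record may arrive as a 1-bp interval or a wider junction
#' interval; the pipeline's convention is that the breakpoint position is
#' the interval midpoint, `floor((start + end)/2)` in 0-based coordinates.
#'
#' @param regions a `GRanges` of breakpoint records.
#' @return A `GRanges` of width-1 positions (metadata preserved).
#' @export
breakpointPositions <- function(regions) {
    # 0-based midpoint floor((s0+e0)/2); in 1-based closed terms that is
    # floor((start-1 + end)/2) + 1
    pos <- floor((GenomicRanges::start(regions) - 1L +
                  GenomicRanges::end(regions)) / 2) + 1L
    out <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(regions),
        IRanges::IRanges(start = pos, width = 1L),
        seqinfo = GenomeInfoDb::seqinfo(regions))
    S4Vectors::mcols(out) <- S4Vectors::mcols(regions)
    out
}
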