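#' Screen every motif variant against every breakpoint set
#'
#' Runs one [permTest()] per (variant x breakpoint set x window width)
#' combination and collects the results into a screen table. Each
#' combination uses a seed derived by stable hashing from `baseSeed` and the
#' combination's identity, so any single combination can be re-run in
#' isolation ([comboTestSeed()]) and reproduce its row exactly.
#'
#' A row is flagged `significant` by the raw rule
#' `p < 0.05 AND (z < -3 OR z > 3)` — no multiple-testing correction enters
#' the flag; Benjamini-Hochberg q-values over each (label x width) stratum
#' are reported alongside for honest reading of a 1024-variant screen. A
#' combination that errors is recorded as a row with `status` holding the
#' message, never dropped silently.
#'
#' @param variants concrete variant sequences: a [Biostrings::DNAStringSet]
#'   as returned by [expandDegenerate()] (names are variant ids) or a
#'   character vector.
#' @param breakpointSets named list of `GRanges` of width-1 breakpoint
#'   positions; names are the set labels (e.g. cancer types).
#' @param widths integer vector of total window widths in bp
#'   (default `c(100, 500)`).
#' @param assembly a [GenomeAssembly-class] with sequence.
#' @param nPerm permutations per test; default 1000.
#' @param baseSeed integer seed from which per-combination seeds are derived.
#' @param strandMode passed to [scanMotif()].
#' @param alternative,randomize,perChromosome passed to [permTest()].
#' @return A data.frame sorted by p-value then decreasing |z|, with columns
#'   `variant_id`, `variant_seq`, `cancer_label`, `window_width`,
#'   `n_windows`, `n_hits`, `observed`, `perm_mean`, `perm_sd`, `z_score`,
#'   `p_value`, `q_value`, `significant`, `n_perm`, `seed`, `status`.
#' @seealso [summarizeSignificance()], [consensusMotif()]
#' @export
screenAll <- function(variants, breakpointSets, widths = c(100L, 500L),
                      assembly, nPerm = 1000, baseSeed = 1,
                      strandMode = c("forward", "both"),
                      alternative = c("auto", "greater", "less"),
                      randomize = c("windows", "hits"),
                      perChromosome = FALSE) {
    strandMode <- match.arg(strandMode)
    alternative <- match.arg(alternative)
    randomize <- match.arg(randomize)
    if (length(variants) == 0L || length(breakpointSets) == 0L ||
        length(widths) == 0L)
        stop("need at least one variant, one breakpoint set and one width")
    if (is.null(names(breakpointSets)))
        stop("breakpointSets must be a named list")
    seqs <- as.character(variants)
    ids <- names(variants)
    if (is.null(ids))
        ids <- as.character(seq_along(seqs))
    rows <- vector("list", length(seqs) * length(breakpointSets) *
                   length(widths))
    k <- 0L
    for (vi in seq_along(seqs)) {
        hits <- suppressWarnings(scanMotif(assembly, seqs[vi], strandMode))
        for (label in names(breakpointSets)) {
            for (w in widths) {
                k <- k + 1L
                seed <- comboTestSeed(baseSeed, ids[vi], label, w)
                rows[[k]] <- tryCatch({
                    windows <- makeWindows(breakpointSets[[label]], w,
                                           assembly)
                    res <- suppressWarnings(permTest(windows, hits, assembly,
                        nPerm = nPerm, seed = seed,
                        alternative = alternative, randomize = randomize,
                        perChromosome = perChromosome))
                    data.frame(
                        variant_id = as.integer(ids[vi]),
                        variant_seq = seqs[vi],
                        cancer_label = label,
                        window_width = as.integer(w),
                        n_windows = res@nWindows,
                        n_hits = res@nHits,
                        observed = res@observed,
                        perm_mean = res@permMean,
                        perm_sd = res@permSd,
                        z_score = res@zScore,
                        p_value = res@pValue,
                        n_perm = res@nPerm,
                        seed = seed,
                        status = "ok",
                        stringsAsFactors = FALSE)
                }, error = function(e) data.frame(
                    variant_id = suppressWarnings(as.integer(ids[vi])),
                    variant_seq = seqs[vi],
                    cancer_label = label,
                    window_width = as.integer(w),
                    n_windows = NA_integer_, n_hits = NA_integer_,
                    observed = NA_integer_,
                    perm_mean = NA_real_, perm_sd = NA_real_,
                    z_score = NA_real_, p_value = NA_real_,
                    n_perm = as.integer(nPerm), seed = seed,
                    status = paste0("error: ", conditionMessage(e)),
                    stringsAsFactors = FALSE))
            }
        }
    }
    tab <- do.call(rbind, rows)
    tab$q_value <- NA_real_
    for (label in unique(tab$cancer_label)) {
        for (w in unique(tab$window_width)) {
            sel <- tab$cancer_label == label & tab$window_width == w &
                   !is.na(tab$p_value)
            tab$q_value[sel] <- stats::p.adjust(tab$p_value[sel],
                                                method = "BH")
        }
    }
    tab$significant <- !is.na(tab$p_value) & tab$p_value < 0.05 &
        !is.na(tab$z_score) & abs(tab$z_score) > 3
    tab <- tab[, c("variant_id", "variant_seq", "cancer_label",
                   "window_width", "n_windows", "n_hits", "observed",
                   "perm_mean", "perm_sd", "z_score", "p_value", "q_value",
                   "significant", "n_perm", "seed", "status")]
    ord <- order(tab$p_value, -abs(tab$z_score), tab$variant_id,
                 tab$cancer_label, tab$window_width, na.last = TRUE)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    tab
}

#' Seed for one screen combination
#'
#' The per-combination seed used by [screenAll()], derived by stable hashing
#' so a single (variant, label, width) test can be reproduced in isolation
#' with [permTest()].
#'
#' @param baseSeed the screen's base seed.
#' @param variantId variant identifier (as used in the screen).
#' @param label breakpoint-set label.
#' @param width window width in bp.
#' @return integer seed below 2^31.
#' @export
comboTestSeed <- function(baseSeed, variantId, label, width) {
    comboSeed(baseSeed, variantId, label, width)
}

#' Pool per-combination significance into per-variant summaries
#'
#' A variant can be called significant per combination, in at least one
#' (label x width) combination, or in every tested combination; all three
#' readings are reported.
#'
#' @param screen a screen table from [screenAll()].
#' @return data.frame with one row per variant: `variant_id`, `variant_seq`,
#'   `n_combinations`, `n_significant`, `significant_any`,
#'   `significant_all`.
#' @export
summarizeSignificance <- function(screen) {
    sp <- split(screen, screen$variant_seq)
    out <- do.call(rbind, lapply(sp, function(d) data.frame(
        variant_id = d$variant_id[1L],
        variant_seq = d$variant_seq[1L],
        n_combinations = nrow(d),
        n_significant = sum(d$significant),
        significant_any = any(d$significant),
        significant_all = all(d$significant),
        stringsAsFactors = FALSE)))
    out <- out[order(out$variant_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a screen table as TSV
#'
#' Tab-separated with header, the stable on-disk form of a screen; numeric
#' formatting is deterministic so identical screens serialize to identical
#' bytes.
#'
#' @param screen a screen table from [screenAll()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScreenTable <- function(screen, path) {
    utils::write.table(screen, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
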