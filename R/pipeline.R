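# End-to-end pipeline drivers with a stable on-disk layout. These are the
# programmatic equivalents of shell subcommands; inst/cli/dsbmotifs.R wraps
# them for shell use.

#' Expand a motif and write the variant manifest
#'
#' @param motif degenerate IUPAC pattern.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the manifest data.frame (`variant_id`, `sequence`);
#'   written to `<outDir>/variants.tsv`.
#' @export
runExpand <- function(motif = PRDM9_MOTIF, outDir) {
    variants <- expandDegenerate(motif)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- data.frame(variant_id = as.integer(names(variants)),
                           sequence = as.character(variants),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(outDir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(length(variants), " variant(s) of ", motif)
    invisible(manifest)
}

#' Scan a genome for all variants and write per-variant BEDs
#'
#' Writes `<outDir>/hits/<motif>.<variant_id>.<sequence>.bed` per variant,
#' a union BED of all hits, and `<outDir>/scan_manifest.tsv` with per-variant
#' hit counts.
#'
#' @param assembly a [GenomeAssembly-class] with sequence, or a path to a
#'   FASTA file.
#' @param motif degenerate IUPAC pattern.
#' @param outDir output directory.
#' @param strandMode passed to [scanMotif()].
#' @return Invisibly, the scan manifest data.frame.
#' @export
runScan <- function(assembly, motif = PRDM9_MOTIF, outDir,
                    strandMode = c("forward", "both")) {
    strandMode <- match.arg(strandMode)
    if (is.character(assembly))
        assembly <- readGenomeFasta(assembly)
    scan <- scanAllVariants(assembly, motif, strandMode)
    hitsDir <- file.path(outDir, "hits")
    dir.create(hitsDir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(scan$manifest))) {
        writeBed(scan$variants[[i]],
                 file.path(hitsDir, sprintf("%s.%d.%s.bed", motif,
                           scan$manifest$variant_id[i],
                           scan$manifest$sequence[i])))
    }
    writeBed(scan$union, file.path(hitsDir, paste0(motif, ".union.bed")))
    utils::write.table(scan$manifest, file.path(outDir, "scan_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(scan$manifest)
}

#' Run the full screen and write its outputs
#'
#' The end-to-end analysis: expand the motif, scan the genome once per
#' variant, build breakpoint-centered windows at every width, permutation
#' test every combination, and write `screen.tsv` plus, for the top hit of
#' each (label x width), a local z-score profile under `localz/` (and a
#' null-histogram figure under `figures/` when `plots = TRUE`).
#'
#' @param assembly a [GenomeAssembly-class] with sequence, or a FASTA path.
#' @param breakpointSets named list of `GRanges` of breakpoint positions, or
#'   a named character vector of BED paths (midpoints are taken per the
#'   package convention).
#' @param outDir output directory.
#' @param motif degenerate IUPAC pattern.
#' @param widths window widths (bp).
#' @param nPerm permutations per combination.
#' @param baseSeed base seed for the per-combination seed derivation.
#' @param strandMode,alternative,randomize,perChromosome forwarded to
#'   [screenAll()].
#' @param plots write figures? Off by default so headless runs need no
#'   graphics device.
#' @return Invisibly, the screen table.
#' @export
runScreen <- function(assembly, breakpointSets, outDir, motif = PRDM9_MOTIF,
                      widths = c(100L, 500L), nPerm = 1000, baseSeed = 1,
                      strandMode = c("forward", "both"),
                      alternative = c("auto", "greater", "less"),
                      randomize = c("windows", "hits"),
                      perChromosome = FALSE, plots = FALSE) {
    strandMode <- match.arg(strandMode)
    if (is.character(assembly))
        assembly <- readGenomeFasta(assembly)
    if (is.character(breakpointSets)) {
        paths <- breakpointSets
        breakpointSets <- lapply(paths, function(p)
            breakpointPositions(readBed(p, assembly)))
        names(breakpointSets) <- names(paths)
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    variants <- expandDegenerate(motif)
    screen <- screenAll(variants, breakpointSets, widths, assembly,
                        nPerm = nPerm, baseSeed = baseSeed,
                        strandMode = strandMode, alternative = alternative,
                        randomize = randomize,
                        perChromosome = perChromosome)
    writeScreenTable(screen, file.path(outDir, "screen.tsv"))
    utils::write.table(summarizeSignificance(screen),
                       file.path(outDir, "screen_by_variant.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    localzDir <- file.path(outDir, "localz")
    dir.create(localzDir, showWarnings = FALSE)
    if (plots)
        dir.create(file.path(outDir, "figures"), showWarnings = FALSE)
    ok <- screen[screen$status == "ok" & !is.na(screen$z_score), ]
    for (label in names(breakpointSets)) {
        for (w in widths) {
            top <- ok[ok$cancer_label == label & ok$window_width == w, ]
            if (nrow(top) == 0L)
                next
            top <- top[1L, ]  # screen is sorted by p then |z|
            hits <- suppressWarnings(
                scanMotif(assembly, top$variant_seq, strandMode))
            windows <- makeWindows(breakpointSets[[label]], w, assembly)
            res <- suppressWarnings(permTest(windows, hits, assembly,
                nPerm = nPerm, seed = top$seed, alternative = alternative,
                randomize = randomize, perChromosome = perChromosome))
            prof <- localZScore(res, windows, hits, assembly)
            utils::write.table(as.data.frame(prof),
                file.path(localzDir, sprintf("%s_%d_%d.tsv", label, w,
                                             top$variant_id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
            if (plots) {
                grDevices::png(file.path(outDir, "figures",
                    sprintf("%s_%d_%d_%%01d.png", label, w,
                            top$variant_id)), width = 700, height = 500)
                plotPermTest(res)
                plotLocalZ(prof)
                grDevices::dev.off()
            }
        }
    }
    invisible(screen)
}

#' Generate the synthetic study fixture (pipeline wrapper)
#'
#' @param outDir output directory.
#' @param profile a [studyProfile()].
#' @param config a [syntheticConfig()].
#' @return Invisibly, the [makeStudyFixture()] bundle.
#' @export
runSimulate <- function(outDir, profile = studyProfile(),
                        config = syntheticConfig(nChroms = 3L,
                                                 chromLength = 2000000L)) {
    makeStudyFixture(outDir, profile, config)
}
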