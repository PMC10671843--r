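#' Configuration for the synthetic study generator
#'
#' Bundles the knobs of the synthetic data that stand in for a real genome
#' plus mapped structural-variant breakpoints: an i.i.d. background genome
#' at a chosen GC content, `nPlantedSites` non-overlapping occurrences of a
#' chosen concrete motif variant written into it, and breakpoint sets in
#' which each breakpoint is, independently with probability
#' `enrichmentFraction`, placed within `proximityDistance` bp of a planted
#' site (else uniformly on the genome).
#'
#' The defaults define the package's reference geometry — a 2 x 2.5 Mb
#' (5 Mb) assembly at GC 0.41 with 300 planted copies of the star variant
#' `CCACCATCACCAC` and 60 breakpoints — used throughout the calibration and
#' power checks.
#'
#' @param nChroms number of chromosomes.
#' @param chromLength length of each chromosome in bp.
#' @param gcContent background GC fraction in (0, 1).
#' @param motif degenerate parent motif (IUPAC).
#' @param plantedVariant concrete expansion to plant; must match `motif`.
#' @param nPlantedSites number of planted, non-overlapping occurrences.
#' @param nBreakpoints breakpoints per generated set.
#' @param enrichmentFraction probability in `[0, 1]` that a breakpoint is
#'   tied to a planted site.
#' @param proximityDistance max distance (bp) from a planted-site center at
#'   which an enriched breakpoint is placed.
#' @param seed integer seed driving the generator.
#' @return A validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nChroms = 2L, chromLength = 2500000L,
                            gcContent = 0.41, motif = PRDM9_MOTIF,
                            plantedVariant = "CCACCATCACCAC",
                            nPlantedSites = 300L, nBreakpoints = 60L,
                            enrichmentFraction = 0, proximityDistance = 50L,
                            seed = 1L) {
    if (nChroms < 1L || chromLength < 1L)
        stop("need at least one chromosome of positive length")
    if (gcContent <= 0 || gcContent >= 1)
        stop("gcContent must lie in (0, 1)")
    if (enrichmentFraction < 0 || enrichmentFraction > 1)
        stop("enrichmentFraction must lie in [0, 1]")
    if (proximityDistance < 0)
        stop("proximityDistance must be >= 0")
    if (nPlantedSites < 0 || nBreakpoints < 0)
        stop("counts must be >= 0")
    chars <- .checkIupac(motif)
    variant <- toupper(plantedVariant)
    if (nchar(variant) != length(chars))
        stop("plantedVariant length does not match motif")
    vchars <- strsplit(variant, "")[[1L]]
    ok <- mapply(function(v, m) grepl(v, .IUPAC[[m]], fixed = TRUE),
                 vchars, chars)
    if (!all(ok))
        stop("plantedVariant is not an expansion of the motif (position ",
             which(!ok)[1L], ")")
    if (nPlantedSites * nchar(variant) > 0.2 * nChroms * chromLength)
        stop("planted sites would cover too much of the genome; ",
             "enlarge it or plant fewer sites")
    structure(list(
        nChroms = as.integer(nChroms),
        chromLength = as.integer(chromLength),
        gcContent = gcContent,
        motif = paste(chars, collapse = ""),
        plantedVariant = variant,
        nPlantedSites = as.integer(nPlantedSites),
        nBreakpoints = as.integer(nBreakpoints),
        enrichmentFraction = enrichmentFraction,
        proximityDistance = as.integer(proximityDistance),
        seed = as.integer(seed)
    ), class = "SyntheticConfig")
}

#' Generate a synthetic genome with planted motif sites
#'
#' Draws each chromosome as i.i.d. bases with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`, then writes `nPlantedSites` non-overlapping
#' copies of the planted variant at uniformly chosen positions (rejecting
#' positions that would overlap an already-planted site). The background is
#' *not* scrubbed of chance motif occurrences: real genomes contain
#' background matches too, and the permutation test must stay powerful
#' despite them. The truth positions let tests condition on planted sites
#' only.
#'
#' Deterministic given `config$seed`.
#'
#' @param config a [syntheticConfig()].
#' @return A list with elements `assembly` (a [GenomeAssembly-class] with
#'   sequence) and `truthSites` (a sorted `GRanges` of the planted
#'   occurrences).
#' @export
generateGenome <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    m <- nchar(config$plantedVariant)
    withSeed(config$seed, {
        gc <- config$gcContent
        probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
        seqs <- vapply(seq_len(config$nChroms), function(i)
            paste(sample(names(probs), config$chromLength, replace = TRUE,
                         prob = probs), collapse = ""),
            character(1))
        names(seqs) <- paste0("chr", seq_len(config$nChroms))
        sites_chr <- integer(0)
        sites_start0 <- numeric(0)
        if (config$nPlantedSites > 0L) {
            nvalid <- config$chromLength - m + 1
            attempts <- 0L
            while (length(sites_chr) < config$nPlantedSites) {
                attempts <- attempts + 1L
                if (attempts > 100000L)
                    stop("could not place all planted sites without overlap; ",
                         "use a larger genome or fewer sites")
                ci <- sample.int(config$nChroms, 1L)
                s0 <- floor(stats::runif(1L) * nvalid)
                clash <- sites_chr == ci &
                         abs(sites_start0 - s0) < m
                if (any(clash))
                    next
                sites_chr <- c(sites_chr, ci)
                sites_start0 <- c(sites_start0, s0)
            }
            for (k in seq_along(sites_chr)) {
                substr(seqs[sites_chr[k]], sites_start0[k] + 1,
                       sites_start0[k] + m) <- config$plantedVariant
            }
        }
        assembly <- assemblyFromSequences(seqs)
        truth <- GenomicRanges::GRanges(
            names(seqs)[sites_chr],
            IRanges::IRanges(start = sites_start0 + 1, width = m),
            seqinfo = assembly@seqinfo)
        list(assembly = assembly,
             truthSites = GenomicRanges::sort(truth, ignore.strand = TRUE))
    })
}

#' Generate a synthetic breakpoint set
#'
#' Each of `nBreakpoints` positions is, independently with probability
#' `enrichmentFraction`, drawn uniformly from
#' `[site_center - d, site_center + d]` around a uniformly chosen planted
#' site (clipped to the chromosome), else uniformly on the genome
#' (chromosome chosen proportionally to length). The true origin of every
#' breakpoint is recorded in the `enriched` metadata column.
#'
#' Deterministic given `seed` (default: derived from `config$seed` so that
#' genome and breakpoints use distinct streams).
#'
#' @param config a [syntheticConfig()].
#' @param truthSites the planted-site `GRanges` from [generateGenome()].
#' @param assembly the matching [GenomeAssembly-class].
#' @param seed integer seed for the breakpoint stream.
#' @return A sorted `GRanges` of width-1 breakpoint positions with logical
#'   metadata column `enriched`.
#' @export
generateBreakpoints <- function(config, truthSites, assembly,
                                seed = comboSeed(config$seed, "breakpoints")) {
    stopifnot(inherits(config, "SyntheticConfig"))
    if (config$enrichmentFraction > 0 && length(truthSites) == 0L)
        stop("enrichmentFraction > 0 requires planted sites")
    n <- config$nBreakpoints
    d <- config$proximityDistance
    len <- chromLengths(assembly)
    withSeed(seed, {
        enriched <- stats::runif(n) < config$enrichmentFraction
        chrom <- character(n)
        pos0 <- numeric(n)
        ne <- sum(enriched)
        if (ne > 0L) {
            si <- sample.int(length(truthSites), ne, replace = TRUE)
            site <- truthSites[si]
            center0 <- floor((GenomicRanges::start(site) - 1 +
                              GenomicRanges::end(site)) / 2)
            sc <- as.character(GenomicRanges::seqnames(site))
            off <- floor(stats::runif(ne) * (2 * d + 1)) - d
            chrom[enriched] <- sc
            pos0[enriched] <- pmin(pmax(center0 + off, 0), len[sc] - 1)
        }
        nb <- sum(!enriched)
        if (nb > 0L) {
            ci <- sample.int(length(len), nb, replace = TRUE, prob = len)
            chrom[!enriched] <- names(len)[ci]
            pos0[!enriched] <- floor(stats::runif(nb) * len[ci])
        }
        gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = pos0 + 1, width = 1L),
            seqinfo = assembly@seqinfo)
        S4Vectors::mcols(gr)$enriched <- enriched
        GenomicRanges::sort(gr, ignore.strand = TRUE)
    })
}

#' Default multi-label study profile
#'
#' Four breakpoint sets whose labels and relative sizes echo a typical
#' four-cancer breakpoint study (breast, lung adenocarcinoma, ovarian, head
#' and neck; the ovarian set largest), scaled to desk size, on a 3 x 2 Mb
#' genome.
#'
#' @param nBreakpoints named integer vector: breakpoints per label.
#' @param enrichmentFraction per-label enrichment (recycled).
#' @return A list understood by [makeStudyFixture()].
#' @export
studyProfile <- function(nBreakpoints = c(BRC = 150L, LUAD = 170L,
                                          OV = 230L, HN = 170L),
                         enrichmentFraction = 0.5) {
    if (is.null(names(nBreakpoints)))
        stop("nBreakpoints must be named by label")
    list(nBreakpoints = nBreakpoints,
         enrichmentFraction = rep_len(enrichmentFraction,
                                      length(nBreakpoints)))
}

#' Write a complete synthetic study fixture to disk
#'
#' One genome, one breakpoint BED per label, the planted-site truth BED, a
#' chrom.sizes table and a manifest TSV recording every parameter and
#' derived seed. Re-running with the same seed reproduces every file
#' byte-identically.
#'
#' @param dir output directory (created if needed).
#' @param profile a [studyProfile()].
#' @param config base [syntheticConfig()]; its `nBreakpoints` and
#'   `enrichmentFraction` are overridden per label by the profile. The
#'   default uses a 3 x 2 Mb genome.
#' @return Invisibly, a list with the `config`, the per-label breakpoint
#'   `GRanges`, the truth sites, the assembly and the file `paths`.
#' @export
makeStudyFixture <- function(dir,
                             profile = studyProfile(),
                             config = syntheticConfig(nChroms = 3L,
                                                      chromLength = 2000000L)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gen <- generateGenome(config)
    paths <- list(
        genome = file.path(dir, "genome.fa"),
        chromSizes = file.path(dir, "genome.chrom.sizes"),
        truth = file.path(dir, "truth_sites.bed"),
        manifest = file.path(dir, "manifest.tsv"))
    writeGenomeFasta(gen$assembly, paths$genome)
    utils::write.table(
        data.frame(chrom = chromNames(gen$assembly),
                   length = chromLengths(gen$assembly)),
        paths$chromSizes, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeBed(gen$truthSites, paths$truth)
    sets <- list()
    manifest <- data.frame(parameter = character(0), value = character(0))
    add <- function(m, p, v) rbind(m, data.frame(parameter = p,
                                                 value = as.character(v)))
    for (p in c("nChroms", "chromLength", "gcContent", "motif",
                "plantedVariant", "nPlantedSites", "proximityDistance",
                "seed"))
        manifest <- add(manifest, p, config[[p]])
    for (i in seq_along(profile$nBreakpoints)) {
        label <- names(profile$nBreakpoints)[i]
        cfg <- config
        cfg$nBreakpoints <- as.integer(profile$nBreakpoints[i])
        cfg$enrichmentFraction <- profile$enrichmentFraction[i]
        seed <- comboSeed(config$seed, "breakpoints", label)
        bp <- generateBreakpoints(cfg, gen$truthSites, gen$assembly,
                                  seed = seed)
        path <- file.path(dir, paste0(label, ".breakpoints.bed"))
        writeBed(bp, path)
        sets[[label]] <- bp
        paths[[paste0("breakpoints_", label)]] <- path
        manifest <- add(manifest, paste0("nBreakpoints.", label),
                        cfg$nBreakpoints)
        manifest <- add(manifest, paste0("enrichmentFraction.", label),
                        cfg$enrichmentFraction)
        manifest <- add(manifest, paste0("seed.", label), seed)
    }
    utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(list(config = config, breakpointSets = sets,
                   truthSites = gen$truthSites, assembly = gen$assembly,
                   paths = paths))
}
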