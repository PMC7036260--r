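# End-to-end driver: simulate (optional) -> profile -> focal -> minimal
# region -> TSS expression -> report. Stage-tagged logging to stderr,
# machine-readable JSON summaries on disk.

pipelineDefaults <- function() {
    list(
        seed = 1L,
        outDir = ".",
        binSize = 50000,
        totalReads = 5e6,
        noise = "negative_binomial",
        dispersion = 0.05,
        nCarriers = 14L,
        nControls = 20L,
        core = list(chrom = "cfs1", start = 20e6, end = 20.5e6),
        lengthRange = c(1e6, 3e6),
        jitter = 1.5e6,
        cnRange = c(8, 12),
        tfRange = c(0.2, 0.6),
        segAlpha = 0.01,
        minBins = 5L,
        nPerm = 1000L,
        candidateThreshold = 0.55,
        alphaBroad = 0.05,
        alphaFocal = 0.01,
        focalMaxLength = 2e7,
        focalMinLog2 = 0.2,
        focalMaxArmFraction = 0.25,
        tss = FALSE,
        tssTrainPerClass = 200L,
        tssTestPerClass = 100L)
}

#' Assemble and validate a pipeline configuration
#'
#' @param config named list of settings, or the path of a YAML file holding
#'   one; keys not among the defaults are rejected. CLI-style overrides in
#'   \code{...} take precedence over the file/list.
#' @param ... individual overrides.
#' @return complete validated configuration list.
#' @export
runConfig <- function(config = list(), ...) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    over <- list(...)
    def <- pipelineDefaults()
    unknown <- setdiff(c(names(config), names(over)), names(def))
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(utils::modifyList(def, config), over)
    with(cfg, {
        stopifnot(binSize > 0, totalReads > 0, candidateThreshold > 0,
                  alphaBroad > 0, alphaFocal > 0, focalMaxLength > 0,
                  focalMinLog2 > 0, nPerm > 0, minBins > 0)
    })
    cfg
}

stageLog <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the whole pipeline on a simulated cohort
#'
#' Simulates a carrier/control cohort on the synthetic mini-genome, builds
#' GC-corrected log2 profiles against the control baseline, segments the
#' carriers, calls focal amplifications, delineates the minimal amplified
#' region, estimates tumor fractions, optionally adds TSS expression
#' calls, and writes BED/TSV/JSON artifacts under \code{config$outDir}.
#'
#' @param config a [runConfig()] (or list/YAML path coercible to one).
#' @return invisibly, a list with the in-memory results (\code{cohort},
#'   \code{segments}, \code{events}, \code{region}, \code{tumorFractions},
#'   and \code{tssCalls} when enabled).
#' @export
runPipeline <- function(config = runConfig()) {
    cfg <- runConfig(config)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    stageLog("config", "seed=", cfg$seed, " outDir=", cfg$outDir)

    stageLog("simulate", cfg$nCarriers, " carriers, ", cfg$nControls,
             " controls")
    bins <- makeBins(miniGenome(), binSize = cfg$binSize,
                     seed = cfg$seed + 1000L)
    core <- GenomicRanges::GRanges(cfg$core$chrom,
                                   IRanges::IRanges(cfg$core$start,
                                                    cfg$core$end))
    spec <- simulationSpec(totalReads = cfg$totalReads, noise = cfg$noise,
                           dispersion = cfg$dispersion, seed = cfg$seed)
    cohort <- simulateCohort(bins, core, nCarriers = cfg$nCarriers,
                             nControls = cfg$nControls,
                             lengthRange = cfg$lengthRange,
                             jitter = cfg$jitter, cnRange = cfg$cnRange,
                             tfRange = cfg$tfRange, spec = spec)

    stageLog("profile", "GC correction and baseline normalization")
    depth <- gcCorrect(cohort$counts)
    baseline <- baselineFromControls(depth[, cohort$controlIds,
                                           drop = FALSE])
    profiles <- lapply(cohort$carrierIds, function(id)
        computeLog2(depth[, id], baseline, bins, sampleId = id))
    names(profiles) <- cohort$carrierIds

    stageLog("segment", "alpha=", cfg$segAlpha, " minBins=", cfg$minBins)
    arms <- armsFromCentromeres(miniGenome())
    segs <- lapply(seq_along(profiles), function(i)
        segmentProfile(profiles[[i]], alpha = cfg$segAlpha,
                       minBins = cfg$minBins, nPerm = cfg$nPerm,
                       seed = cfg$seed + i))
    names(segs) <- cohort$carrierIds

    stageLog("focal", "calling focal amplifications")
    fp <- focalParams(maxLength = cfg$focalMaxLength,
                      maxArmFraction = cfg$focalMaxArmFraction,
                      minLog2 = cfg$focalMinLog2)
    events <- do.call(c, unname(lapply(segs, callFocalEvents, arms = arms,
                                       params = fp)))
    writeBedRanges(events, file.path(cfg$outDir, "focal_events.bed"),
                   scoreFrom = "meanLog2")

    stageLog("minregion", "chromosome ", cfg$core$chrom)
    region <- minimalAmplifiedRegion(profiles, events, cfg$core$chrom,
                                     threshold = cfg$candidateThreshold,
                                     alphaBroad = cfg$alphaBroad,
                                     alphaFocal = cfg$alphaFocal)
    utils::write.table(as.data.frame(windowStats(region)),
                       file.path(cfg$outDir, "window_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    regionJson <- list(
        seed = cfg$seed, nCarriers = region@nCarriers,
        diagnostic = region@diagnostic,
        broadPeak = peakCoords(broadPeak(region)),
        focalPeak = peakCoords(focalPeak(region)))
    jsonlite::write_json(regionJson,
                         file.path(cfg$outDir, "minimal_region.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")

    stageLog("tf", "tumor-fraction estimation")
    segs <- lapply(segs, estimateTumorFraction)
    tf <- vapply(segs, tumorFraction, numeric(1))
    jsonlite::write_json(list(seed = cfg$seed, tumorFraction = as.list(tf)),
                         file.path(cfg$outDir, "tumor_fraction.json"),
                         auto_unbox = TRUE, digits = NA)

    tssCalls <- NULL
    if (isTRUE(cfg$tss)) {
        stageLog("tss-expr", "footprint simulation and classification")
        nTot <- cfg$tssTrainPerClass + cfg$tssTestPerClass
        tspec <- tssFootprintSpec(nGenes = c(expressed = nTot,
                                             repressed = nTot),
                                  seed = cfg$seed + 77L)
        tm <- simulateTSSCoverage(tspec)
        norm <- tssNormalize(tm)
        feats <- tssFeatures(norm)
        info <- geneInfo(tm)
        trainGenes <- c(info$gene[info$class == "expressed"][
                            seq_len(cfg$tssTrainPerClass)],
                        info$gene[info$class == "unexpressed"][
                            seq_len(cfg$tssTrainPerClass)])
        training <- stats::setNames(
            ifelse(info$class[match(trainGenes, info$gene)] == "expressed",
                   "expressed", "unexpressed"), trainGenes)
        tssCalls <- classifyExpression(feats, training,
                                       seed = cfg$seed + 78L)
        utils::write.table(as.data.frame(tssCalls),
                           file.path(cfg$outDir, "tss_calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }

    summary <- list(seed = cfg$seed,
                    nCarriers = cfg$nCarriers, nControls = cfg$nControls,
                    nFocalEvents = length(events),
                    broadPeak = peakCoords(broadPeak(region)),
                    focalPeak = peakCoords(focalPeak(region)),
                    meanTumorFraction = mean(tf))
    jsonlite::write_json(summary, file.path(cfg$outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    stageLog("done", "artifacts in ", cfg$outDir)
    invisible(list(cohort = cohort, segments = segs, events = events,
                   region = region, tumorFractions = tf,
                   tssCalls = tssCalls))
}

# 1-based inclusive human-facing peak coordinates, or NULL when empty.
peakCoords <- function(gr) {
    if (length(gr) == 0L) return(NULL)
    list(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}
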