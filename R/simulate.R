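# Synthetic cfDNA generator: binned coverage under a two-component
# tumor/normal mixture with GC bias and sampling noise, cohorts of carriers
# sharing an amplified core, and nucleosome footprints around TSSs.

# Run code under a temporary RNG state; NULL seed leaves the RNG alone.
withLocalSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    force(code)
}

#' Quadratic GC bias curve
#'
#' Unimodal relative-efficiency curve peaking at \code{peak} and clipped to
#' \code{[floor, 1]}; the default emulates the mild coverage bias of
#' low-coverage whole-genome libraries.
#'
#' @param peak GC fraction of maximal efficiency.
#' @param floor minimal relative efficiency.
#' @param halfWidth GC distance at which the curve reaches \code{floor}.
#' @return a function mapping GC fraction to relative efficiency.
#' @export
#' @examples
#' f <- gcBiasQuadratic(); f(0.45); f(0.2)
gcBiasQuadratic <- function(peak = 0.45, floor = 0.7, halfWidth = 0.55) {
    force(peak); force(floor); force(halfWidth)
    function(gc) pmax(floor, pmin(1, 1 - (1 - floor) * ((gc - peak) / halfWidth)^2))
}

#' Simulation settings for binned cfDNA coverage
#'
#' @param tumorFraction fraction of plasma DNA derived from tumor cells,
#'   in \code{[0, 1]}.
#' @param totalReads total read count to distribute over bins (default 5e6,
#'   the lower end of a typical shallow plasma WGS run).
#' @param gcBias function of GC fraction giving relative bin efficiency.
#' @param noise \code{"negative_binomial"} (default; overdispersion is the
#'   rule in shallow WGS), \code{"poisson"}, or \code{"none"} (rounded
#'   expectation, for noiseless oracles).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed integer seed; \code{NULL} uses the current RNG stream.
#' @return a validated list of class \code{SimulationSpec}.
#' @export
simulationSpec <- function(tumorFraction = 0, totalReads = 5e6,
                           gcBias = gcBiasQuadratic(),
                           noise = c("negative_binomial", "poisson", "none"),
                           dispersion = 0.05, seed = NULL) {
    noise <- match.arg(noise)
    if (!is.numeric(tumorFraction) || length(tumorFraction) != 1L ||
        is.na(tumorFraction) || tumorFraction < 0 || tumorFraction > 1)
        stop("tumorFraction must be a single value in [0, 1]")
    if (!is.numeric(totalReads) || totalReads <= 0)
        stop("totalReads must be positive")
    if (dispersion < 0) stop("dispersion must be non-negative")
    structure(list(tumorFraction = tumorFraction, totalReads = totalReads,
                   gcBias = gcBias, noise = noise, dispersion = dispersion,
                   seed = seed),
              class = "SimulationSpec")
}

#' Tile chromosomes into fixed-size bins
#'
#' Tiles each chromosome into consecutive windows of \code{binSize} bp
#' (the last bin of a chromosome may be shorter) and attaches a GC fraction
#' and mappability flag per bin.
#'
#' @param chromLengths named vector of chromosome lengths (bp).
#' @param binSize window size in bp (default 50,000).
#' @param gc per-bin GC fractions (recycled/checked against the number of
#'   bins), or \code{NULL} to generate a smooth synthetic GC landscape.
#' @param seed seed for the generated GC landscape (ignored when \code{gc}
#'   is supplied).
#' @return \code{GRanges} bin grid with \code{gc} and \code{mappable}
#'   metadata columns, sorted by (chrom, start).
#' @export
#' @examples
#' bins <- makeBins(c(chrA = 150e3), binSize = 50e3)
#' length(bins)  # 3
makeBins <- function(chromLengths, binSize = 50000, gc = NULL, seed = NULL) {
    if (!is.numeric(binSize) || length(binSize) != 1L || binSize <= 0)
        stop("binSize must be a positive number")
    if (is.null(names(chromLengths)) || any(chromLengths <= 0))
        stop("chromLengths must be a named vector of positive lengths")
    nPer <- as.integer(ceiling(chromLengths / binSize))
    starts <- unlist(lapply(nPer, function(n) (seq_len(n) - 1) * binSize + 1),
                     use.names = FALSE)
    ends <- unlist(mapply(function(n, len) pmin(seq_len(n) * binSize, len),
                          nPer, chromLengths, SIMPLIFY = FALSE),
                   use.names = FALSE)
    gr <- GenomicRanges::GRanges(rep(names(chromLengths), nPer),
                                 IRanges::IRanges(starts, ends))
    GenomeInfoDb::seqlengths(gr) <- chromLengths
    n <- length(gr)
    if (is.null(gc)) {
        gc <- withLocalSeed(seed, {
            unlist(lapply(nPer, function(nb) {
                phase <- stats::runif(1, 0, 2 * pi)
                base <- 0.45 + 0.06 * sin(2 * pi * seq_len(nb) / 60 + phase)
                rough <- stats::rnorm(nb, 0, 0.05)
                w <- min(9L, if (nb %% 2L == 1L) nb else nb - 1L)
                sm <- if (w >= 3L)
                    as.numeric(stats::filter(rough, rep(1 / w, w),
                                             sides = 2, circular = TRUE))
                else rough
                pmin(0.58, pmax(0.32, base + sm))
            }), use.names = FALSE)
        })
    }
    if (length(gc) != n) stop("gc must supply one value per bin")
    if (any(gc < 0 | gc > 1)) stop("gc must lie in [0, 1]")
    S4Vectors::mcols(gr)$gc <- as.numeric(gc)
    S4Vectors::mcols(gr)$mappable <- TRUE
    gr
}

#' Construct a copy-number truth set
#'
#' @param chrom,start,end event coordinates (1-based inclusive).
#' @param cn absolute tumor-cell copy number (integer >= 0); ploidy is 2
#'   everywhere else.
#' @param chromLengths optional named lengths to validate bounds against.
#' @return \code{GRanges} with a \code{cn} metadata column.
#' @export
scnaTruth <- function(chrom = character(), start = integer(),
                      end = integer(), cn = integer(),
                      chromLengths = NULL) {
    stopifnot(length(chrom) == length(start), length(start) == length(end),
              length(end) == length(cn))
    if (any(cn < 0)) stop("cn must be >= 0")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    S4Vectors::mcols(gr)$cn <- as.numeric(cn)
    if (length(gr) > 1L) {
        red <- GenomicRanges::reduce(gr)
        if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(gr)))
            stop("truth events must not overlap")
    }
    if (!is.null(chromLengths)) {
        bad <- end > chromLengths[as.character(chrom)]
        if (any(bad)) stop("truth events exceed chromosome bounds")
    }
    gr
}

# Tumor copy number of each bin: the cn of the event containing the bin
# midpoint, ploidy 2 elsewhere.
binCopyNumber <- function(bins, truth) {
    cn <- rep(2, length(bins))
    if (length(truth) == 0L) return(cn)
    mids <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(bins),
        IRanges::IRanges(GenomicRanges::start(bins) +
                         floor((GenomicRanges::width(bins) - 1) / 2),
                         width = 1L))
    GenomeInfoDb::seqlevels(mids) <- unique(c(GenomeInfoDb::seqlevels(mids),
                                              GenomeInfoDb::seqlevels(truth)))
    hit <- suppressWarnings(GenomicRanges::findOverlaps(mids, truth))
    cn[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(truth)$cn[S4Vectors::subjectHits(hit)]
    cn
}

#' Expected bin counts under the tumor/normal mixture
#'
#' The expected count of bin b is \code{totalReads * w_b} with
#' \code{w_b} proportional to \code{gcBias(gc_b) * (1 - tf + tf * cn_b / 2)}
#' and normalized to sum to one.
#'
#' @param bins bin grid from [makeBins()].
#' @param truth \code{GRanges} truth set from [scnaTruth()].
#' @param spec a [simulationSpec()].
#' @return numeric vector of expected counts (sums to \code{totalReads}).
#' @export
expectedCounts <- function(bins, truth, spec) {
    stopifnot(inherits(spec, "SimulationSpec"))
    if (length(truth) > 0L &&
        !all(as.character(GenomicRanges::seqnames(truth)) %in%
             as.character(GenomeInfoDb::seqlevels(bins))))
        stop("truth events must lie on the bin grid's chromosomes")
    cn <- binCopyNumber(bins, truth)
    w <- spec$gcBias(S4Vectors::mcols(bins)$gc) *
        (1 - spec$tumorFraction + spec$tumorFraction * cn / 2)
    spec$totalReads * w / sum(w)
}

#' Simulate a binned cfDNA coverage profile
#'
#' Draws per-bin read counts around the mixture expectation of
#' [expectedCounts()] under the spec's noise model. Identical seeds give
#' identical profiles.
#'
#' @inheritParams expectedCounts
#' @param sampleId column name of the resulting sample.
#' @return a [BinnedCounts-class] with one sample column.
#' @export
simulateProfile <- function(bins, truth, spec, sampleId = "sample1") {
    mu <- expectedCounts(bins, truth, spec)
    counts <- withLocalSeed(spec$seed, drawCounts(mu, spec))
    newBinnedCounts(bins, matrix(counts, ncol = 1,
                                 dimnames = list(NULL, sampleId)))
}

drawCounts <- function(mu, spec) {
    switch(spec$noise,
        poisson = stats::rpois(length(mu), mu),
        negative_binomial = {
            if (spec$dispersion == 0) stats::rpois(length(mu), mu)
            else stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion)
        },
        none = round(mu))
}

newBinnedCounts <- function(bins, countMatrix) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = countMatrix), rowRanges = bins)
    methods::new("BinnedCounts", se)
}

#' Simulate a patient cohort sharing an amplified core region
#'
#' Each carrier receives one focal amplification whose boundaries are
#' independently jittered but always contain the shared \code{core}; copy
#' number and tumor fraction are drawn per carrier. Carriers may
#' additionally carry a broad whole-chromosome background gain on the core
#' chromosome, as seen in real amplicon carriers. Controls are tumor-free
#' profiles (they double as the baseline panel).
#'
#' @param bins bin grid from [makeBins()].
#' @param core \code{GRanges} of length 1: the shared amplified core.
#' @param nCarriers,nControls cohort composition (defaults 14 and 136,
#'   a 150-sample cohort).
#' @param lengthRange carrier event length range in bp.
#' @param jitter maximal boundary offset (bp) of an event edge from the
#'   core edge.
#' @param cnRange integer range of carrier event copy numbers.
#' @param tfRange carrier tumor-fraction range.
#' @param backgroundGain list(prob, cn): probability and copy number of a
#'   whole-chromosome background gain on the core chromosome in carriers;
#'   \code{NULL} disables it.
#' @param spec a [simulationSpec()]; its \code{tumorFraction} is ignored
#'   (drawn per carrier), its \code{seed} drives all draws.
#' @return list of class \code{CohortSim}: \code{counts} (multi-sample
#'   [BinnedCounts-class]), \code{truth} (list of per-carrier truth
#'   \code{GRanges}), \code{tumorFractions}, \code{carrierIds},
#'   \code{controlIds}, \code{core}.
#' @export
simulateCohort <- function(bins, core, nCarriers = 14, nControls = 136,
                           lengthRange = c(1e6, 3e6), jitter = 1.5e6,
                           cnRange = c(8, 12), tfRange = c(0.2, 0.6),
                           backgroundGain = list(prob = 0.7, cn = 3),
                           spec = simulationSpec()) {
    stopifnot(length(core) == 1L)
    chrom <- as.character(GenomicRanges::seqnames(core))
    chromLen <- GenomeInfoDb::seqlengths(bins)[chrom]
    if (is.na(chromLen)) stop("core chromosome absent from the bin grid")
    coreLen <- GenomicRanges::width(core)
    if (coreLen > chromLen) stop("core longer than its chromosome")
    if (max(lengthRange) < coreLen)
        stop("lengthRange must accommodate the core length")
    lengthRange[1] <- max(lengthRange[1], coreLen)

    withLocalSeed(spec$seed, {
        carrierIds <- sprintf("carrier%02d", seq_len(nCarriers))
        controlIds <- sprintf("control%03d", seq_len(nControls))
        truth <- vector("list", nCarriers)
        names(truth) <- carrierIds
        tfs <- stats::runif(nCarriers, tfRange[1], tfRange[2])
        counts <- matrix(0L, nrow = length(bins),
                         ncol = nCarriers + nControls,
                         dimnames = list(NULL, c(carrierIds, controlIds)))
        for (i in seq_len(nCarriers)) {
            len <- stats::runif(1, lengthRange[1], lengthRange[2])
            slack <- len - coreLen
            leftExt <- stats::runif(1, 0, min(jitter, slack))
            evStart <- max(1, round(GenomicRanges::start(core) - leftExt))
            evEnd <- min(chromLen, round(evStart + len - 1))
            evStart <- min(evStart, GenomicRanges::start(core))
            evEnd <- max(evEnd, GenomicRanges::end(core))
            cn <- sample(seq(cnRange[1], cnRange[2]), 1L)
            ev <- GenomicRanges::GRanges(chrom,
                                         IRanges::IRanges(evStart, evEnd))
            S4Vectors::mcols(ev)$cn <- cn
            if (!is.null(backgroundGain) &&
                stats::runif(1) < backgroundGain$prob) {
                bg <- GenomicRanges::GRanges(
                    chrom, IRanges::IRanges(1, chromLen))
                S4Vectors::mcols(bg)$cn <- backgroundGain$cn
                left <- GenomicRanges::setdiff(bg, ev)
                S4Vectors::mcols(left)$cn <- backgroundGain$cn
                ev <- sort(c(ev, left))
            }
            truth[[i]] <- ev
            si <- simulationSpec(tumorFraction = tfs[i],
                                 totalReads = spec$totalReads,
                                 gcBias = spec$gcBias, noise = spec$noise,
                                 dispersion = spec$dispersion, seed = NULL)
            counts[, i] <- drawCounts(expectedCounts(bins, ev, si), si)
        }
        normSpec <- simulationSpec(tumorFraction = 0,
                                   totalReads = spec$totalReads,
                                   gcBias = spec$gcBias, noise = spec$noise,
                                   dispersion = spec$dispersion, seed = NULL)
        muNorm <- expectedCounts(bins, GenomicRanges::GRanges(), normSpec)
        for (j in seq_len(nControls))
            counts[, nCarriers + j] <- drawCounts(muNorm, normSpec)
        structure(list(counts = newBinnedCounts(bins, counts),
                       truth = truth, tumorFractions = tfs,
                       carrierIds = carrierIds, controlIds = controlIds,
                       core = core),
                  class = "CohortSim")
    })
}

#' Settings for simulated TSS nucleosome footprints
#'
#' @param nGenes named vector: genes per class
#'   (\code{c(expressed = , repressed = )}).
#' @param depth mean per-base coverage (default 5, a deep plasma WGS
#'   operating point).
#' @param ndrDepletion multiplicative coverage dip over the
#'   nucleosome-depleted region [-150, +50] of expressed genes, in [0, 1].
#' @param nucleosomePeriod phasing period (bp) of flanking nucleosomes.
#' @param phasingAmplitude amplitude of the phased oscillation, as a
#'   fraction of \code{depth}; 0 disables phasing.
#' @param noiseSd per-base Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return a validated list of class \code{TSSFootprintSpec}.
#' @export
tssFootprintSpec <- function(nGenes = c(expressed = 300, repressed = 300),
                             depth = 5, ndrDepletion = 0.5,
                             nucleosomePeriod = 190, phasingAmplitude = 0.1,
                             noiseSd = 0.5, seed = NULL) {
    if (depth <= 0) stop("depth must be positive")
    if (ndrDepletion < 0 || ndrDepletion > 1)
        stop("ndrDepletion must lie in [0, 1]")
    if (!all(c("expressed", "repressed") %in% names(nGenes)))
        stop("nGenes must name 'expressed' and 'repressed' counts")
    structure(list(nGenes = nGenes, depth = depth,
                   ndrDepletion = ndrDepletion,
                   nucleosomePeriod = nucleosomePeriod,
                   phasingAmplitude = phasingAmplitude,
                   noiseSd = noiseSd, seed = seed),
              class = "TSSFootprintSpec")
}

#' Simulate TSS coverage footprints with known expression truth
#'
#' Expressed genes show a nucleosome-depleted region (a multiplicative dip
#' over [-150, +50]) and phased oscillation of the flanking nucleosomes;
#' repressed genes show flat coverage. Gaussian per-base noise is added to
#' both and coverage is floored at zero.
#'
#' @param spec a [tssFootprintSpec()].
#' @return a [TSSCoverageMatrix-class]; \code{geneInfo()} carries the truth
#'   \code{class} label per gene.
#' @export
simulateTSSCoverage <- function(spec = tssFootprintSpec()) {
    stopifnot(inherits(spec, "TSSFootprintSpec"))
    pos <- -3000:3000
    ndrMask <- as.numeric(pos >= -150 & pos <= 50)
    expr <- spec$depth * (1 - spec$ndrDepletion * ndrMask) +
        spec$phasingAmplitude * spec$depth *
        cos(2 * pi * pos / spec$nucleosomePeriod) * (1 - ndrMask)
    repr <- rep(spec$depth, length(pos))
    nE <- spec$nGenes[["expressed"]]
    nR <- spec$nGenes[["repressed"]]
    withLocalSeed(spec$seed, {
        mk <- function(template, n) {
            m <- matrix(rep(template, each = n), nrow = n)
            if (spec$noiseSd > 0)
                m <- m + matrix(stats::rnorm(n * length(pos), 0, spec$noiseSd),
                                nrow = n)
            pmax(m, 0)
        }
        cov <- rbind(mk(expr, nE), mk(repr, nR))
        genes <- S4Vectors::DataFrame(
            gene = c(sprintf("exprGene%03d", seq_len(nE)),
                     sprintf("reprGene%03d", seq_len(nR))),
            class = rep(c("expressed", "unexpressed"), c(nE, nR)))
        rownames(cov) <- genes$gene
        methods::new("TSSCoverageMatrix", coverage = cov,
                     positions = as.integer(pos), genes = genes,
                     flankNormalized = FALSE)
    })
}
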