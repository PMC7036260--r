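# Plasma-Seq stage: GC correction, baseline normalization, log2 ratios,
# mixture algebra and a grid-search tumor-fraction estimator.

# Bins retained for analysis: mappable and GC within gcRange.
binMask <- function(bins, gcRange = c(0.3, 0.6)) {
    gc <- S4Vectors::mcols(bins)$gc
    S4Vectors::mcols(bins)$mappable & gc >= gcRange[1] & gc <= gcRange[2]
}

#' GC-correct binned counts to normalized depth
#'
#' Fits the count-versus-GC trend over unmasked bins (local regression by
#' default, or a median-per-GC-decile fallback), divides counts by the
#' trend, and rescales so the corrected depth averages 1 over unmasked
#' bins. Masked bins (unmappable or GC outside \code{gcRange}) are NA.
#'
#' @param bc a [BinnedCounts-class].
#' @param method \code{"loess"} or \code{"decile"}.
#' @param span loess span.
#' @param gcRange GC interval outside which bins are masked.
#' @return numeric matrix (bins x samples) of normalized depth, NA where
#'   masked.
#' @export
gcCorrect <- function(bc, method = c("loess", "decile"), span = 0.75,
                      gcRange = c(0.3, 0.6)) {
    method <- match.arg(method)
    stopifnot(methods::is(bc, "BinnedCounts"))
    bins <- SummarizedExperiment::rowRanges(bc)
    counts <- SummarizedExperiment::assay(bc, "counts")
    keep <- binMask(bins, gcRange)
    if (sum(keep) < 100) stop("need at least 100 unmasked bins")
    gc <- S4Vectors::mcols(bins)$gc
    out <- matrix(NA_real_, nrow = nrow(counts), ncol = ncol(counts),
                  dimnames = dimnames(counts))
    for (j in seq_len(ncol(counts))) {
        y <- as.numeric(counts[keep, j])
        if (all(y == 0)) stop("empty profile (all counts zero) in sample ",
                              colnames(counts)[j])
        x <- gc[keep]
        trend <- switch(method,
            loess = {
                # robust fit: aberrant (gained/lost) bins must not drag
                # the GC trend of a tumor sample
                fit <- stats::loess(y ~ x, span = span, degree = 2,
                                    family = "symmetric")
                stats::predict(fit, newdata = data.frame(x = x))
            },
            decile = {
                dec <- cut(x, stats::quantile(x, probs = seq(0, 1, 0.1)),
                           include.lowest = TRUE)
                med <- tapply(y, dec, stats::median)
                as.numeric(med[dec])
            })
        trend <- pmax(trend, 1e-8 * mean(y))
        d <- y / trend
        out[keep, j] <- d / mean(d)
    }
    out
}

#' Median baseline from a panel of control profiles
#'
#' @param controlDepth matrix of GC-corrected normalized depths
#'   (bins x controls), as returned by [gcCorrect()].
#' @param minControls minimum panel size (default 5).
#' @return numeric vector: per-bin median control depth (NA where masked).
#' @export
baselineFromControls <- function(controlDepth, minControls = 5) {
    if (ncol(controlDepth) < minControls)
        stop("baseline requires at least ", minControls, " control profiles")
    apply(controlDepth, 1, stats::median)
}

#' Per-bin log2 ratio of a sample against the baseline
#'
#' \code{log2(sample / baseline)} with a pseudo-depth floor of 1e-3: bins
#' where the baseline or the sample depth falls below the floor are masked
#' (NA), as are bins masked upstream.
#'
#' @param sampleDepth numeric vector or single-column matrix of GC-corrected
#'   sample depth.
#' @param baseline per-bin baseline depth from [baselineFromControls()].
#' @param bins the common bin grid (\code{GRanges}).
#' @param sampleId sample label.
#' @param floor pseudo-depth floor.
#' @return a [Log2Profile-class].
#' @export
computeLog2 <- function(sampleDepth, baseline, bins, sampleId = "sample1",
                        floor = 1e-3) {
    sampleDepth <- as.numeric(sampleDepth)
    if (length(sampleDepth) != length(bins) ||
        length(baseline) != length(bins))
        stop("sample, baseline and bin grid lengths differ (grid mismatch)")
    masked <- is.na(sampleDepth) | is.na(baseline) |
        baseline < floor | sampleDepth < floor
    l2 <- rep(NA_real_, length(bins))
    l2[!masked] <- log2(sampleDepth[!masked] / baseline[!masked])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = matrix(l2, ncol = 1,
                                    dimnames = list(NULL, sampleId))),
        rowRanges = bins)
    methods::new("Log2Profile", se)
}

#' Forward two-component mixture map: copy number to expected log2 ratio
#'
#' @param cn absolute tumor copy number.
#' @param tf tumor fraction in [0, 1].
#' @return \code{log2(1 - tf + tf * cn / 2)}.
#' @export
log2FromCn <- function(cn, tf) {
    if (any(tf < 0 | tf > 1)) stop("tf must lie in [0, 1]")
    log2(1 - tf + tf * cn / 2)
}

#' Invert the mixture: observed log2 ratio to absolute copy number
#'
#' @param meanLog2 observed mean log2 ratio.
#' @param tf tumor fraction in (0, 1].
#' @return continuous copy-number estimate, clipped at 0.
#' @export
cnFromLog2 <- function(meanLog2, tf) {
    if (any(tf <= 0))
        stop("copy number undefined at zero tumor fraction")
    if (any(tf > 1)) stop("tf must lie in (0, 1]")
    pmax(0, (2^meanLog2 * 2 - 2 * (1 - tf)) / tf)
}

#' Estimate tumor fraction from segment mean log2 ratios
#'
#' Grid search over tf in [0.05, 1] (step 0.005) minimizing the
#' bin-weighted squared distance between each segment's mean log2 and the
#' nearest mixture value \code{log2(1 - tf + tf * cn / 2)} over integer
#' copy numbers 0..\code{maxCn}. A profile without aberrant segments
#' (all |mean log2| below \code{neutralTol}) returns tf 0 with flag
#' \code{"no aberration"}; exact ties across the grid return the smallest
#' tf with flag \code{"ambiguous"}.
#'
#' @param segs a [SegmentSet-class].
#' @param maxCn largest copy number in the model grid.
#' @param neutralTol |log2| below which a segment counts as neutral.
#' @return the [SegmentSet-class] with \code{tumorFraction}, \code{tfFlag}
#'   and a per-segment integer \code{cn} metadata column filled in.
#' @export
estimateTumorFraction <- function(segs, maxCn = 8, neutralTol = 0.05) {
    stopifnot(methods::is(segs, "SegmentSet"))
    gr <- segs@segments
    if (length(gr) < 1L) stop("need at least one segment")
    ml <- S4Vectors::mcols(gr)$meanLog2
    nb <- S4Vectors::mcols(gr)$nBins
    if (all(abs(ml) < neutralTol)) {
        S4Vectors::mcols(gr)$cn <- rep(2L, length(gr))
        segs@segments <- gr
        segs@tumorFraction <- 0
        segs@tfFlag <- "no aberration"
        return(segs)
    }
    tfGrid <- seq(0.05, 1, by = 0.005)
    cnGrid <- 0:maxCn
    rss <- vapply(tfGrid, function(tf) {
        model <- log2(pmax(1 - tf + tf * cnGrid / 2, 1e-4))
        sum(nb * (apply(outer(ml, model, function(a, b) (a - b)^2), 1, min)))
    }, numeric(1))
    best <- min(rss)
    ties <- which(rss <= best + 1e-12)
    tf <- tfGrid[ties[1]]
    model <- log2(pmax(1 - tf + tf * cnGrid / 2, 1e-4))
    cn <- cnGrid[apply(outer(ml, model, function(a, b) abs(a - b)), 1,
                       which.min)]
    S4Vectors::mcols(gr)$cn <- as.integer(cn)
    segs@segments <- gr
    segs@tumorFraction <- tf
    segs@tfFlag <- if (length(ties) > 1L) "ambiguous" else "ok"
    segs
}
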