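#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges granges findOverlaps countOverlaps seqnames start end width
#' @importFrom GenomeInfoDb seqlengths seqlevels seqnames<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges assay assays colData
NULL

#' BinnedCounts: raw read counts in fixed genome windows
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are the fixed
#' (default 50-kb) genome windows of a bin grid and whose columns are
#' samples. The single assay \code{"counts"} holds non-negative integer
#' read counts; \code{rowRanges()} carries per-bin \code{gc} (GC fraction)
#' and \code{mappable} (logical) metadata columns.
#'
#' @seealso [makeBins()], [simulateProfile()], [gcCorrect()]
#' @export
setClass("BinnedCounts", contains = "RangedSummarizedExperiment")

setValidity("BinnedCounts", function(object) {
    msg <- character()
    if (!"counts" %in% names(SummarizedExperiment::assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(cnt)) || any(cnt < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (!all(c("gc", "mappable") %in% colnames(S4Vectors::mcols(rr))))
        msg <- c(msg, "rowRanges must carry 'gc' and 'mappable' columns")
    else {
        gc <- S4Vectors::mcols(rr)$gc
        if (any(gc < 0 | gc > 1, na.rm = TRUE))
            msg <- c(msg, "gc must lie in [0, 1]")
    }
    if (is.unsorted(order(as.integer(GenomicRanges::seqnames(rr)),
                          GenomicRanges::start(rr))))
        msg <- c(msg, "bins must be sorted by (chrom, start)")
    if (length(msg)) msg else TRUE
})

#' Log2Profile: per-bin log2 ratios against a control baseline
#'
#' A \linkS4class{RangedSummarizedExperiment} over the same bin grid as the
#' originating \linkS4class{BinnedCounts}, with a single assay
#' \code{"log2"}. Masked bins (unmappable, extreme GC, or baseline/sample
#' depth under the pseudo-depth floor) are \code{NA}.
#'
#' @seealso [computeLog2()], [segmentProfile()]
#' @export
setClass("Log2Profile", contains = "RangedSummarizedExperiment")

setValidity("Log2Profile", function(object) {
    if (!"log2" %in% names(SummarizedExperiment::assays(object)))
        return("assay 'log2' is required")
    l2 <- SummarizedExperiment::assay(object, "log2")
    if (any(!is.finite(l2) & !is.na(l2)))
        return("unmasked log2 values must be finite (masked bins are NA)")
    TRUE
})

#' SegmentSet: piecewise-constant segments of a log2 profile
#'
#' Holds the segments produced by [segmentProfile()] for one sample, as a
#' \code{GRanges} with metadata columns \code{sampleId}, \code{meanLog2},
#' \code{nBins} and (after [estimateTumorFraction()]) integer \code{cn},
#' together with the tumor-fraction estimate and a diagnostic flag.
#'
#' @slot segments a \code{GRanges} of segments.
#' @slot tumorFraction estimated tumor fraction, \code{NA} until estimated.
#' @slot tfFlag \code{"ok"}, \code{"no aberration"}, \code{"ambiguous"} or
#'   \code{"not estimated"}.
#' @export
setClass("SegmentSet",
    representation(segments = "GRanges",
                   tumorFraction = "numeric",
                   tfFlag = "character"),
    prototype(tumorFraction = NA_real_, tfFlag = "not estimated"))

setValidity("SegmentSet", function(object) {
    msg <- character()
    need <- c("sampleId", "meanLog2", "nBins")
    if (!all(need %in% colnames(S4Vectors::mcols(object@segments))))
        msg <- c(msg, paste("segments need mcols:", paste(need, collapse = ", ")))
    tf <- object@tumorFraction
    if (length(tf) != 1L || (!is.na(tf) && (tf < 0 || tf > 1)))
        msg <- c(msg, "tumorFraction must be a single value in [0,1] or NA")
    if (length(msg)) msg else TRUE
})

#' MinimalRegion: Fisher-exact broad and focal peaks over candidate windows
#'
#' Result of the minimal-amplified-region procedure: the broad peak
#' (Fisher p < 0.05) and the nested focal peak (p < 0.01), each the union
#' of contiguous significant candidate windows, plus the per-window
#' statistics table.
#'
#' @slot broadPeak \code{GRanges} of length 0 or 1.
#' @slot focalPeak \code{GRanges} of length 0 or 1, contained in the broad peak.
#' @slot windowStats \code{DataFrame}: one row per window of the target
#'   chromosome with \code{medianLog2}, \code{candidate}, \code{eventCount},
#'   \code{fisherP}.
#' @slot nCarriers number of carrier samples.
#' @slot params list of thresholds used.
#' @slot diagnostic character; \code{"ok"} or why peaks are empty.
#' @export
setClass("MinimalRegion",
    representation(broadPeak = "GRanges",
                   focalPeak = "GRanges",
                   windowStats = "DataFrame",
                   nCarriers = "integer",
                   params = "list",
                   diagnostic = "character"))

setValidity("MinimalRegion", function(object) {
    msg <- character()
    if (length(object@broadPeak) > 1L || length(object@focalPeak) > 1L)
        msg <- c(msg, "peaks must each be a single (possibly empty) range")
    if (length(object@focalPeak) == 1L) {
        if (length(object@broadPeak) != 1L)
            msg <- c(msg, "focal peak requires a broad peak")
        else {
            hit <- suppressWarnings(
                GenomicRanges::findOverlaps(object@focalPeak,
                                            object@broadPeak,
                                            type = "within"))
            if (length(hit) != 1L)
                msg <- c(msg, "focal peak must lie within the broad peak")
        }
    }
    if (length(msg)) msg else TRUE
})

#' TSSCoverageMatrix: strand-oriented coverage around transcription starts
#'
#' Per-base coverage for a set of genes at positions -3000..+3000 relative
#' to the TSS, oriented so that positive positions are downstream on the
#' coding strand. Rows are genes, columns positions.
#'
#' @slot coverage numeric matrix, genes x 6001 positions.
#' @slot positions integer vector of relative positions (-3000..3000).
#' @slot genes \code{DataFrame} with at least a \code{gene} column; the
#'   simulator adds the truth \code{class} label.
#' @slot flankNormalized logical; TRUE after [tssNormalize()].
#' @export
setClass("TSSCoverageMatrix",
    representation(coverage = "matrix",
                   positions = "integer",
                   genes = "DataFrame",
                   flankNormalized = "logical"),
    prototype(flankNormalized = FALSE))

setValidity("TSSCoverageMatrix", function(object) {
    msg <- character()
    if (ncol(object@coverage) != length(object@positions))
        msg <- c(msg, "coverage columns must match positions")
    if (nrow(object@coverage) != nrow(object@genes))
        msg <- c(msg, "coverage rows must match gene table")
    if (any(object@coverage < 0, na.rm = TRUE))
        msg <- c(msg, "coverage must be non-negative")
    if (length(msg)) msg else TRUE
})
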