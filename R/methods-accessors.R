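#' @describeIn SegmentSet-class segments as a \code{GRanges}.
#' @export
setMethod("segments", "SegmentSet", function(x, ...) x@segments)

#' @describeIn SegmentSet-class estimated tumor fraction (NA until estimated).
#' @export
setMethod("tumorFraction", "SegmentSet", function(x) x@tumorFraction)

#' @describeIn SegmentSet-class diagnostic flag of the tf estimate.
#' @export
setMethod("tfFlag", "SegmentSet", function(x) x@tfFlag)

setMethod("show", "SegmentSet", function(object) {
    seg <- object@segments
    cat("SegmentSet with", length(seg), "segments",
        "for sample", unique(S4Vectors::mcols(seg)$sampleId)[1], "\n")
    if (!is.na(object@tumorFraction))
        cat("  tumor fraction:", format(object@tumorFraction, digits = 3),
            sprintf("(%s)\n", object@tfFlag))
    else
        cat("  tumor fraction: not estimated\n")
    invisible(NULL)
})

#' @describeIn MinimalRegion-class broad (p < alphaBroad) peak.
#' @export
setMethod("broadPeak", "MinimalRegion", function(x) x@broadPeak)

#' @describeIn MinimalRegion-class focal (p < alphaFocal) peak.
#' @export
setMethod("focalPeak", "MinimalRegion", function(x) x@focalPeak)

#' @describeIn MinimalRegion-class per-window statistics table.
#' @export
setMethod("windowStats", "MinimalRegion", function(x) x@windowStats)

setMethod("show", "MinimalRegion", function(object) {
    fmt <- function(gr) {
        if (length(gr) == 0L) return("none")
        sprintf("%s:%s-%s", as.character(GenomicRanges::seqnames(gr)),
                format(GenomicRanges::start(gr), big.mark = ","),
                format(GenomicRanges::end(gr), big.mark = ","))
    }
    cat("MinimalRegion over", object@nCarriers, "carriers\n")
    cat("  broad peak (p <", object@params$alphaBroad, "):",
        fmt(object@broadPeak), "\n")
    cat("  focal peak (p <", object@params$alphaFocal, "):",
        fmt(object@focalPeak), "\n")
    if (object@diagnostic != "ok") cat("  note:", object@diagnostic, "\n")
    invisible(NULL)
})

#' @describeIn TSSCoverageMatrix-class relative positions (bp from TSS).
#' @export
setMethod("tssPositions", "TSSCoverageMatrix", function(x) x@positions)

#' @describeIn TSSCoverageMatrix-class the genes x positions coverage matrix.
#' @export
setMethod("tssCoverage", "TSSCoverageMatrix", function(x) x@coverage)

#' @describeIn TSSCoverageMatrix-class gene annotation table.
#' @export
setMethod("geneInfo", "TSSCoverageMatrix", function(x) x@genes)

setMethod("show", "TSSCoverageMatrix", function(object) {
    cat("TSSCoverageMatrix:", nrow(object@coverage), "genes x",
        ncol(object@coverage), "positions",
        sprintf("[%d..%d]", min(object@positions), max(object@positions)),
        if (object@flankNormalized) "(flank-normalized)" else "(raw)", "\n")
    invisible(NULL)
})
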