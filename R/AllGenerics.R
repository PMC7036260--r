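#' @rdname SegmentSet-class
#' @param x,object a package object.
#' @param ... passed on.
#' @export
setGeneric("segments", function(x, ...) standardGeneric("segments"))

#' @rdname SegmentSet-class
#' @export
setGeneric("tumorFraction", function(x) standardGeneric("tumorFraction"))

#' @rdname SegmentSet-class
#' @export
setGeneric("tfFlag", function(x) standardGeneric("tfFlag"))

#' @rdname MinimalRegion-class
#' @export
setGeneric("broadPeak", function(x) standardGeneric("broadPeak"))

#' @rdname MinimalRegion-class
#' @export
setGeneric("focalPeak", function(x) standardGeneric("focalPeak"))

#' @rdname MinimalRegion-class
#' @export
setGeneric("windowStats", function(x) standardGeneric("windowStats"))

#' @rdname TSSCoverageMatrix-class
#' @export
setGeneric("tssPositions", function(x) standardGeneric("tssPositions"))

#' @rdname TSSCoverageMatrix-class
#' @export
setGeneric("tssCoverage", function(x) standardGeneric("tssCoverage"))

#' @rdname TSSCoverageMatrix-class
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))
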