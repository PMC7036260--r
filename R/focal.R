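# Restrictive focal-amplification calling and cohort recurrence tables.

#' Thresholds of the restrictive focal-amplicon definition
#'
#' The defaults (at most 20 Mb, at most 25\% of the chromosome arm, mean
#' log2 ratio at least 0.2) are this package's documented reimplementation
#' choices for a restrictive focal-event definition; all are configurable.
#'
#' @param maxLength maximal event length in bp.
#' @param maxArmFraction maximal event length as a fraction of its arm.
#' @param minLog2 minimal |mean log2 ratio| (gains use \code{>= minLog2},
#'   deletions \code{<= -minLog2}).
#' @param minCnOverPloidy optional minimal copy number (requires an
#'   estimated tumor fraction); \code{NULL} disables it.
#' @return list of class \code{FocalParams}.
#' @export
focalParams <- function(maxLength = 2e7, maxArmFraction = 0.25,
                        minLog2 = 0.2, minCnOverPloidy = NULL) {
    if (maxLength <= 0) stop("maxLength must be positive")
    if (minLog2 <= 0) stop("minLog2 must be positive")
    if (maxArmFraction <= 0 || maxArmFraction > 1)
        stop("maxArmFraction must lie in (0, 1]")
    structure(list(maxLength = maxLength, maxArmFraction = maxArmFraction,
                   minLog2 = minLog2, minCnOverPloidy = minCnOverPloidy),
              class = "FocalParams")
}

#' Call focal amplifications (or deletions) from segments
#'
#' A segment is a focal event when it is short (\code{<= maxLength} and
#' \code{<= maxArmFraction} of the arm containing its midpoint) and of high
#' amplitude (mean log2 \code{>= minLog2} for gains; mirrored for
#' deletions, which are reported separately via \code{direction}).
#'
#' @param segs a [SegmentSet-class].
#' @param arms \code{GRanges} arm table with an \code{arm} metadata column
#'   (see [armsFromCentromeres()], [hg19ArmTable()]).
#' @param params a [focalParams()].
#' @param direction \code{"gain"} (default) or \code{"loss"}.
#' @return \code{GRanges} of focal events with \code{sampleId},
#'   \code{meanLog2} and \code{arm} metadata columns.
#' @export
callFocalEvents <- function(segs, arms, params = focalParams(),
                            direction = c("gain", "loss")) {
    direction <- match.arg(direction)
    stopifnot(methods::is(segs, "SegmentSet"))
    if (missing(arms) || is.null(arms)) stop("an arm table is required")
    gr <- segs@segments
    if (length(gr) == 0L) return(annotateArm(gr, arms))
    gr <- annotateArm(gr, arms)
    keep <- !is.na(S4Vectors::mcols(gr)$arm) &
        GenomicRanges::width(gr) <= params$maxLength &
        GenomicRanges::width(gr) <=
            params$maxArmFraction * S4Vectors::mcols(gr)$armLength
    amp <- if (direction == "gain")
        S4Vectors::mcols(gr)$meanLog2 >= params$minLog2
    else S4Vectors::mcols(gr)$meanLog2 <= -params$minLog2
    keep <- keep & amp
    if (!is.null(params$minCnOverPloidy)) {
        cn <- S4Vectors::mcols(gr)$cn
        if (is.null(cn)) stop("minCnOverPloidy requires per-segment cn ",
                              "(run estimateTumorFraction first)")
        keep <- keep & cn / 2 >= params$minCnOverPloidy
    }
    out <- gr[keep]
    S4Vectors::mcols(out)$armLength <- NULL
    out
}

# Assign each segment to the arm containing its midpoint.
annotateArm <- function(gr, arms) {
    if (length(gr) == 0L) {
        S4Vectors::mcols(gr)$arm <- character()
        S4Vectors::mcols(gr)$armLength <- numeric()
        return(gr)
    }
    mids <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr),
        IRanges::IRanges(GenomicRanges::start(gr) +
                         floor((GenomicRanges::width(gr) - 1) / 2),
                         width = 1L))
    GenomeInfoDb::seqlevels(mids) <-
        unique(c(GenomeInfoDb::seqlevels(mids),
                 GenomeInfoDb::seqlevels(arms)))
    hit <- suppressWarnings(GenomicRanges::findOverlaps(mids, arms))
    arm <- rep(NA_character_, length(gr))
    armLen <- rep(NA_real_, length(gr))
    arm[S4Vectors::queryHits(hit)] <-
        S4Vectors::mcols(arms)$arm[S4Vectors::subjectHits(hit)]
    armLen[S4Vectors::queryHits(hit)] <-
        GenomicRanges::width(arms)[S4Vectors::subjectHits(hit)]
    S4Vectors::mcols(gr)$arm <- arm
    S4Vectors::mcols(gr)$armLength <- armLen
    gr
}

#' Cohort recurrence of focal events over regions
#'
#' A sample counts toward a region when any of its focal events overlaps
#' the region by at least one bp; duplicated events within a sample count
#' once.
#'
#' @param events \code{GRanges} of focal events from the whole cohort, with
#'   a \code{sampleId} metadata column.
#' @param regions \code{GRanges} of regions (cytobands, windows, ...); a
#'   \code{name} metadata column is carried through if present.
#' @param cohortN cohort size (denominator).
#' @return \code{data.frame}: region coordinates, \code{carriers},
#'   \code{cohortN}, \code{frequency}.
#' @export
recurrence <- function(events, regions, cohortN) {
    stopifnot(cohortN >= 1)
    hit <- suppressWarnings(
        GenomicRanges::findOverlaps(regions, events, minoverlap = 1L))
    carriers <- vapply(seq_along(regions), function(i) {
        s <- S4Vectors::mcols(events)$sampleId[
            S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == i]]
        length(unique(s))
    }, integer(1))
    data.frame(
        region = if (!is.null(S4Vectors::mcols(regions)$name))
            S4Vectors::mcols(regions)$name
        else sprintf("%s:%d-%d",
                     as.character(GenomicRanges::seqnames(regions)),
                     GenomicRanges::start(regions),
                     GenomicRanges::end(regions)),
        chrom = as.character(GenomicRanges::seqnames(regions)),
        start = GenomicRanges::start(regions),
        end = GenomicRanges::end(regions),
        carriers = carriers,
        cohortN = cohortN,
        frequency = carriers / cohortN,
        stringsAsFactors = FALSE)
}
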