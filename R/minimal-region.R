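# Minimal amplified region: median-log2 candidate windows, per-window
# focal-event frequencies, and Fisher-exact broad/focal peaks.

#' Per-window median log2 ratio across carrier profiles
#'
#' @param profiles list of single-sample [Log2Profile-class] objects on a
#'   common bin grid (or one multi-sample [Log2Profile-class]).
#' @param chrom target chromosome.
#' @param minFraction minimal fraction of carriers that must be unmasked in
#'   a window for its median to be reported; windows below it are NA.
#' @return list: \code{windows} (\code{GRanges} of the chromosome's bins)
#'   and \code{medianLog2} (numeric, NA where missing). The even-count
#'   median is the mean of the two central values.
#' @export
windowMedianLog2 <- function(profiles, chrom, minFraction = 0.5) {
    if (methods::is(profiles, "Log2Profile")) profiles <- list(profiles)
    if (length(profiles) >= 1 && sum(vapply(profiles, function(p)
        ncol(SummarizedExperiment::assay(p, "log2")), integer(1))) < 2)
        stop("need at least 2 carrier profiles")
    bins0 <- SummarizedExperiment::rowRanges(profiles[[1]])
    mats <- lapply(profiles, function(p) {
        b <- SummarizedExperiment::rowRanges(p)
        if (length(b) != length(bins0) ||
            !all(GenomicRanges::start(b) == GenomicRanges::start(bins0)) ||
            !all(as.character(GenomicRanges::seqnames(b)) ==
                 as.character(GenomicRanges::seqnames(bins0))))
            stop("carrier profiles are not on a common grid (grid mismatch)")
        SummarizedExperiment::assay(p, "log2")
    })
    m <- do.call(cbind, mats)
    onChrom <- as.character(GenomicRanges::seqnames(bins0)) == chrom
    if (!any(onChrom)) stop("chromosome ", chrom, " absent from the grid")
    m <- m[onChrom, , drop = FALSE]
    med <- apply(m, 1, function(v) {
        ok <- !is.na(v)
        if (mean(ok) < minFraction) NA_real_ else stats::median(v[ok])
    })
    list(windows = bins0[onChrom], medianLog2 = med)
}

#' Candidate windows by median log2 threshold
#'
#' Strictly greater than the threshold; missing medians are not candidates.
#'
#' @param medianLog2 numeric vector of per-window medians.
#' @param threshold candidacy threshold (default 0.55).
#' @return logical mask.
#' @export
candidateWindows <- function(medianLog2, threshold = 0.55) {
    !is.na(medianLog2) & medianLog2 > threshold
}

#' Per-window focal-event frequency
#'
#' Counts, per window, the distinct carriers having at least one focal
#' event overlapping it by one bp or more.
#'
#' @param events \code{GRanges} of carrier focal events with a
#'   \code{sampleId} metadata column.
#' @param windows \code{GRanges} of windows.
#' @return integer vector of carrier counts per window.
#' @export
windowEventFrequency <- function(events, windows) {
    hit <- suppressWarnings(
        GenomicRanges::findOverlaps(windows, events, minoverlap = 1L))
    vapply(seq_along(windows), function(i) {
        s <- S4Vectors::mcols(events)$sampleId[
            S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == i]]
        length(unique(s))
    }, integer(1))
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value: the sum of the probabilities of
#' all tables (at fixed margins) no more probable than the observed one
#' (with the conventional 1 + 1e-7 tie tolerance).
#'
#' @param a,b,c,d cell counts of the table \code{[[a, b], [c, d]]}.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' fisherP2x2(14, 0, 1, 13)  # 7.478e-07
fisherP2x2 <- function(a, b, c, d) {
    stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
    m <- a + b        # row 1 total
    n <- c + d        # row 2 total
    k <- a + c        # column 1 total
    lo <- max(0L, k - n)
    hi <- min(k, m)
    support <- lo:hi
    dens <- stats::dhyper(support, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    min(1, sum(dens[dens <= pObs * (1 + 1e-7)]))
}

#' Fisher-exact broad and focal peaks over candidate windows
#'
#' The baseline count is the minimum event count among candidate windows.
#' Each candidate window is tested against it with a two-sided Fisher exact
#' test on \code{[[count_w, n - count_w], [m, n - m]]}. The broad peak is
#' the longest contiguous run of windows with p below \code{alphaBroad}
#' (ties resolved leftmost); the focal peak is the longest contiguous
#' sub-run with p below \code{alphaFocal}. Peak coordinates are the union
#' of member windows.
#'
#' @param windows \code{GRanges} of the chromosome's windows.
#' @param medianLog2 per-window carrier medians (see [windowMedianLog2()]).
#' @param candidate logical candidacy mask (see [candidateWindows()]).
#' @param eventCounts per-window carrier event counts (see
#'   [windowEventFrequency()]).
#' @param nCarriers number of carriers.
#' @param alphaBroad,alphaFocal significance levels of the two peak tiers.
#' @param minCandidateRun isolated candidate windows in runs shorter than
#'   this are ignored: a lone noise window far from the amplicon would
#'   otherwise corrupt the baseline count and degenerate the test.
#' @return a [MinimalRegion-class].
#' @export
fisherPeaks <- function(windows, medianLog2, candidate, eventCounts,
                        nCarriers, alphaBroad = 0.05, alphaFocal = 0.01,
                        minCandidateRun = 3) {
    stopifnot(length(windows) == length(candidate),
              length(windows) == length(eventCounts))
    nCarriers <- as.integer(nCarriers)
    candidate <- dropShortRuns(candidate, minCandidateRun)
    p <- rep(NA_real_, length(windows))
    diagnostic <- "ok"
    if (!any(candidate)) {
        diagnostic <- "no candidate windows (no region)"
    } else {
        m <- min(eventCounts[candidate])
        idx <- which(candidate)
        p[idx] <- vapply(eventCounts[idx], function(cw)
            fisherP2x2(cw, nCarriers - cw, m, nCarriers - m), numeric(1))
        if (all(eventCounts[idx] == m))
            diagnostic <- "all candidate counts equal the baseline; no window significant"
    }
    sigBroad <- !is.na(p) & p < alphaBroad
    broadRun <- longestRun(sigBroad)
    broadGr <- runToRange(windows, broadRun)
    focalGr <- GenomicRanges::GRanges()
    if (length(broadRun)) {
        sigFocal <- !is.na(p) & p < alphaFocal
        inBroad <- logical(length(p))
        inBroad[broadRun] <- TRUE
        focalRun <- longestRun(sigFocal & inBroad)
        focalGr <- runToRange(windows, focalRun)
    }
    if (diagnostic == "ok" && length(broadGr) == 0L)
        diagnostic <- "no window significant at alphaBroad"
    stats <- S4Vectors::DataFrame(
        chrom = as.character(GenomicRanges::seqnames(windows)),
        start = GenomicRanges::start(windows),
        end = GenomicRanges::end(windows),
        medianLog2 = medianLog2,
        candidate = candidate,
        eventCount = eventCounts,
        fisherP = p)
    methods::new("MinimalRegion", broadPeak = broadGr, focalPeak = focalGr,
                 windowStats = stats, nCarriers = nCarriers,
                 params = list(alphaBroad = alphaBroad,
                               alphaFocal = alphaFocal),
                 diagnostic = diagnostic)
}

# Remove TRUE runs shorter than minRun from a logical mask.
dropShortRuns <- function(mask, minRun) {
    if (minRun <= 1L || !any(mask)) return(mask)
    r <- rle(mask)
    r$values[r$values & r$lengths < minRun] <- FALSE
    inverse.rle(r)
}

# Indices of the longest TRUE run (ties -> leftmost); integer() when none.
longestRun <- function(mask) {
    if (!any(mask)) return(integer())
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values)
    best <- cand[which.max(r$lengths[cand])]
    seq.int(starts[best], ends[best])
}

runToRange <- function(windows, run) {
    if (length(run) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(windows))[run[1]],
        IRanges::IRanges(min(GenomicRanges::start(windows)[run]),
                         max(GenomicRanges::end(windows)[run])))
}

#' Delineate the minimal amplified region from carrier profiles and events
#'
#' Convenience wrapper chaining [windowMedianLog2()], [candidateWindows()],
#' [windowEventFrequency()] and [fisherPeaks()] on one chromosome.
#'
#' @inheritParams windowMedianLog2
#' @param events \code{GRanges} of carrier focal events (with
#'   \code{sampleId}).
#' @param threshold candidate median-log2 threshold.
#' @param alphaBroad,alphaFocal peak significance levels.
#' @return a [MinimalRegion-class].
#' @export
minimalAmplifiedRegion <- function(profiles, events, chrom,
                                   threshold = 0.55, alphaBroad = 0.05,
                                   alphaFocal = 0.01) {
    med <- windowMedianLog2(profiles, chrom)
    cand <- candidateWindows(med$medianLog2, threshold)
    counts <- windowEventFrequency(events, med$windows)
    nCarriers <- if (methods::is(profiles, "Log2Profile"))
        ncol(SummarizedExperiment::assay(profiles, "log2"))
    else sum(vapply(profiles, function(p)
        ncol(SummarizedExperiment::assay(p, "log2")), integer(1)))
    fisherPeaks(med$windows, med$medianLog2, cand, counts, nCarriers,
                alphaBroad, alphaFocal)
}
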