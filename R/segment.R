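# Recursive circular binary segmentation of log2 profiles. Each step finds
# the arc (sub-interval) whose mean differs most from the rest of the
# segment (a two-sample t-like statistic over all arc placements), accepts
# it when a permutation test is significant, and recurses. Permutation
# scans are pruned through the range of the centred partial-sum bridge,
# and permutations stop early once the p-value is provably above alpha.

# Best arc of x: maximizes |mean(in) - mean(out)| / (s * sqrt(1/m + 1/(n-m))).
# With the bridge Z_k = S_k - k * mean(x) (Z_0 = 0) the statistic for the
# arc (i, j], m = j - i, is |Z_j - Z_i| * sqrt(n / (m (n - m))) / s.
bestArc <- function(x, minBins) {
    n <- length(x)
    if (n < 2L * minBins) return(list(stat = 0, i = NA_integer_,
                                      j = NA_integer_))
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(list(stat = 0, i = NA_integer_,
                                             j = NA_integer_))
    z <- c(0, cumsum(x) - seq_len(n) * mean(x))
    best <- 0; bi <- NA_integer_; bj <- NA_integer_
    for (m in minBins:(n - minBins)) {
        d <- z[(m + 1L):(n + 1L)] - z[1L:(n + 1L - m)]
        k <- which.max(abs(d))
        stat <- abs(d[k]) * sqrt(n / (m * (n - m))) / s
        if (stat > best) {
            best <- stat
            bi <- k - 1L          # arc is (bi, bj] in 1..n coordinates
            bj <- k - 1L + m
        }
    }
    list(stat = best, i = bi, j = bj)
}

# Does a permutation of x reach obsStat? sd and the bridge range prune the
# arc lengths that could possibly reach it, so null permutations are cheap.
arcReaches <- function(xp, minBins, obsStat, s) {
    n <- length(xp)
    z <- c(0, cumsum(xp) - seq_len(n) * mean(xp))
    r <- max(z) - min(z)
    # need |dz| >= obsStat * s * sqrt(m (n - m) / n); |dz| <= r always
    lim <- (r / (obsStat * s))^2 * n
    for (m in minBins:(n - minBins)) {
        mm <- m * (n - m)
        if (mm > lim) next
        d <- z[(m + 1L):(n + 1L)] - z[1L:(n + 1L - m)]
        if (max(abs(d)) >= obsStat * s * sqrt(mm / n)) return(TRUE)
    }
    FALSE
}

# Hybrid significance rule: arcs whose conservative Bonferroni normal
# bound over all arc placements is far below alpha are accepted without
# permuting; otherwise a sequential permutation test runs, stopping as
# soon as the p-value is provably above alpha. Deterministic given the
# RNG state.
arcSignificant <- function(x, obsStat, alpha, nPerm, minBins) {
    n <- length(x)
    bound <- 2 * stats::pnorm(-obsStat) * n^2 / 2
    if (bound < alpha / 100) return(TRUE)
    s <- stats::sd(x)
    exceed <- 0L
    limit <- alpha * (nPerm + 1) - 1   # p < alpha iff exceedances < limit
    for (b in seq_len(nPerm)) {
        if (arcReaches(sample(x), minBins, obsStat, s))
            exceed <- exceed + 1L
        if (exceed >= limit - 1e-9) return(FALSE)
    }
    TRUE
}

segmentIndices <- function(x, alpha, minBins, nPerm) {
    breaks <- integer()
    queue <- list(c(1L, length(x)))
    while (length(queue)) {
        lohi <- queue[[1]]; queue <- queue[-1]
        lo <- lohi[1]; hi <- lohi[2]
        seg <- x[lo:hi]
        arc <- bestArc(seg, minBins)
        if (is.na(arc$i) || arc$stat <= 0) next
        if (!arcSignificant(seg, arc$stat, alpha, nPerm, minBins)) next
        i <- arc$i; j <- arc$j; n <- length(seg)
        if (i > 0L && i < minBins) i <- 0L          # snap short outer parts
        if (j < n && n - j < minBins) j <- n
        newBreaks <- integer()
        if (i > 0L) newBreaks <- c(newBreaks, lo + i - 1L)
        if (j < n) newBreaks <- c(newBreaks, lo + j - 1L)
        if (length(newBreaks) == 0L) next
        breaks <- c(breaks, newBreaks)
        parts <- unique(c(lo - 1L, sort(newBreaks), hi))
        for (p in seq_len(length(parts) - 1L))
            queue <- c(queue, list(c(parts[p] + 1L, parts[p + 1L])))
    }
    sort(unique(breaks))
}

# Local refinement, iterated to a fixed point: re-place each breakpoint
# at the best single split between its neighbouring breakpoints.
refineBreaks <- function(x, breaks, minBins, maxIter = 5L) {
    if (length(breaks) == 0L) return(breaks)
    for (iter in seq_len(maxIter)) {
        bounds <- c(0L, sort(breaks), length(x))
        for (i in seq_along(breaks)) {
            lo <- bounds[i] + 1L
            hi <- bounds[i + 2L]
            seg <- x[lo:hi]
            n <- length(seg)
            if (n < 2L) next
            cs <- cumsum(seg)
            k <- 1L:(n - 1L)
            m1 <- cs[k] / k
            m2 <- (cs[n] - cs[k]) / (n - k)
            t <- abs(m1 - m2) * sqrt((n - k) * k)
            bounds[i + 1L] <- lo + k[which.max(t)] - 1L
        }
        new <- sort(unique(bounds[c(-1L, -length(bounds))]))
        if (identical(new, breaks)) break
        breaks <- new
    }
    breaks
}

# Undo pass: repeatedly remove the breakpoint whose flanking segment means
# are closest (in SE units, with a robust per-bin sd from successive
# differences) while that distance stays below undoSD.
undoSplits <- function(x, breaks, undoSD = 3) {
    if (length(breaks) == 0L) return(breaks)
    s <- stats::mad(diff(x)) / sqrt(2)
    if (!is.finite(s) || s == 0) return(breaks)
    repeat {
        if (length(breaks) == 0L) return(breaks)
        bounds <- c(0L, breaks, length(x))
        sizes <- diff(bounds)
        means <- vapply(seq_along(sizes), function(i)
            mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
        tt <- abs(diff(means)) /
            (s * sqrt(1 / sizes[-length(sizes)] + 1 / sizes[-1]))
        i <- which.min(tt)
        if (tt[i] >= undoSD) return(breaks)
        breaks <- breaks[-i]
    }
}

# Merge segments shorter than minBins into the neighbour with closer mean.
mergeShort <- function(x, breaks, minBins) {
    repeat {
        bounds <- c(0L, breaks, length(x))
        sizes <- diff(bounds)
        short <- which(sizes < minBins)
        if (length(short) == 0L || length(breaks) == 0L) return(breaks)
        i <- short[1]
        means <- vapply(seq_along(sizes), function(s)
            mean(x[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
        dropLeft <- i > 1L &&
            (i == length(sizes) ||
             abs(means[i] - means[i - 1L]) <= abs(means[i] - means[i + 1L]))
        breaks <- setdiff(breaks, bounds[if (dropLeft) i else i + 1L])
    }
}

#' Segment a log2 profile into piecewise-constant regions
#'
#' Recursive circular binary segmentation per chromosome: at each step the
#' arc whose mean most differs from the rest of the current segment (a
#' two-sample t-like statistic, scanned over all arc placements with both
#' sides at least \code{minBins} bins) is accepted when its permutation
#' p-value over \code{nPerm} seeded shuffles falls below \code{alpha}, and
#' the pieces are re-examined recursively. Breakpoints are then locally
#' re-optimized and segments shorter than \code{minBins} merged into the
#' neighbour with the closer mean. Masked (NA) bins are skipped; segment
#' coordinates span their member bins.
#'
#' @param profile a [Log2Profile-class] (single sample).
#' @param alpha significance level of the permutation test.
#' @param minBins minimal segment size in bins.
#' @param nPerm permutations per tested split.
#' @param undoSD undo threshold: adjacent segments whose means differ by
#'   fewer robust standard errors than this are re-merged (guards against
#'   noise-driven fragmentation of true segments).
#' @param seed integer seed making the permutation stream reproducible.
#' @return a [SegmentSet-class].
#' @export
segmentProfile <- function(profile, alpha = 0.01, minBins = 5,
                           nPerm = 1000, undoSD = 3, seed = NULL) {
    stopifnot(methods::is(profile, "Log2Profile"))
    bins <- SummarizedExperiment::rowRanges(profile)
    l2 <- SummarizedExperiment::assay(profile, "log2")
    if (ncol(l2) != 1L)
        stop("segmentProfile expects a single-sample profile")
    sampleId <- colnames(l2)[1]
    l2 <- as.numeric(l2)
    minBins <- as.integer(minBins)
    chroms <- as.character(unique(GenomicRanges::seqnames(bins)))
    withLocalSeed(seed, {
        segList <- lapply(chroms, function(ch) {
            onChrom <- which(as.character(GenomicRanges::seqnames(bins)) == ch)
            idx <- onChrom[!is.na(l2[onChrom])]
            if (length(idx) == 0L) return(NULL)
            x <- l2[idx]
            breaks <- segmentIndices(x, alpha, minBins, nPerm)
            breaks <- refineBreaks(x, breaks, minBins)
            breaks <- undoSplits(x, breaks, undoSD)
            breaks <- refineBreaks(x, breaks, minBins)
            breaks <- mergeShort(x, breaks, minBins)
            bounds <- c(0L, breaks, length(x))
            from <- bounds[-length(bounds)] + 1L
            to <- bounds[-1L]
            GenomicRanges::GRanges(
                ch,
                IRanges::IRanges(GenomicRanges::start(bins)[idx[from]],
                                 GenomicRanges::end(bins)[idx[to]]),
                sampleId = sampleId,
                meanLog2 = vapply(seq_along(from), function(i)
                    mean(x[from[i]:to[i]]), numeric(1)),
                nBins = to - from + 1L)
        })
        segList <- segList[!vapply(segList, is.null, logical(1))]
        gr <- if (length(segList)) suppressWarnings(do.call(c, segList))
              else GenomicRanges::GRanges(sampleId = character(),
                                          meanLog2 = numeric(),
                                          nBins = integer())
        methods::new("SegmentSet", segments = gr,
                     tumorFraction = NA_real_, tfFlag = "not estimated")
    })
}
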