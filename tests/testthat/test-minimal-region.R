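# Minimal amplified region: window medians, candidacy, event frequencies
# and Fisher-exact peak assembly.

nWin <- sum(GenomicRanges::seqnames(testBins) == "tchr1")  # 200 windows

profileWith <- function(values, id) log2ProfileFromValues(
    c(values, rep(0, length(testBins) - nWin)), sampleId = id)

test_that("window medians across carriers use the midpoint convention", {
    p1 <- profileWith(rep(0.2, nWin), "c1")
    p2 <- profileWith(rep(0.6, nWin), "c2")
    p3 <- profileWith(rep(1.0, nWin), "c3")
    med <- windowMedianLog2(list(p1, p2, p3), "tchr1")
    expect_equal(unique(med$medianLog2), 0.6)
    expect_length(med$windows, nWin)

    # 14 carriers, 7 at 0.3 and 7 at 0.9: even-n median = 0.6
    ps <- c(lapply(1:7, function(i) profileWith(rep(0.3, nWin),
                                                paste0("a", i))),
            lapply(1:7, function(i) profileWith(rep(0.9, nWin),
                                                paste0("b", i))))
    med <- windowMedianLog2(ps, "tchr1")
    expect_equal(unique(med$medianLog2), 0.6)

    expect_error(windowMedianLog2(list(p1), "tchr1"), "at least 2")
    short <- computeLog2(rep(1, 10), rep(1, 10),
                         makeBins(c(x = 500e3), seed = 1))
    expect_error(windowMedianLog2(list(p1, short), "tchr1"), "mismatch")
})

test_that("candidate windows require median strictly above the threshold", {
    expect_false(candidateWindows(0.55))
    expect_true(candidateWindows(0.56))
    expect_false(candidateWindows(NA_real_))
    mr <- fisherPeaks(testBins[1:20], rep(0, 20),
                      candidateWindows(rep(0, 20)), rep(0L, 20), 14)
    expect_length(broadPeak(mr), 0L)
    expect_length(focalPeak(mr), 0L)
    expect_match(mr@diagnostic, "no candidate")
})

test_that("event frequency counts distinct carriers per window", {
    win <- testBins[1:10]
    ev <- GenomicRanges::GRanges(
        "tchr1",
        IRanges::IRanges(c(1, 1, 100e3 + 1), c(250e3, 250e3, 400e3)),
        sampleId = c("c1", "c1", "c2"))   # c1 has two overlapping events
    cnt <- windowEventFrequency(ev, win)
    expect_equal(cnt[1], 1L)   # window 1: only c1
    expect_equal(cnt[3], 2L)   # window 3: c1 and c2
    expect_equal(cnt[9], 0L)
})

test_that("fisherP2x2 equals brute-force enumeration and fisher.test", {
    expect_equal(fisherP2x2(14, 0, 1, 13), bruteFisherP(14, 0, 1, 13),
                 tolerance = 1e-12)
    expect_equal(fisherP2x2(14, 0, 1, 13), 7.478201e-07, tolerance = 1e-6)
    expect_lt(fisherP2x2(14, 0, 1, 13), 0.01)
    for (tb in list(c(5, 9, 3, 11), c(0, 8, 8, 0), c(2, 2, 2, 2),
                    c(12, 2, 5, 9))) {
        expect_equal(fisherP2x2(tb[1], tb[2], tb[3], tb[4]),
                     stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                     tolerance = 1e-9)
    }
})

test_that("peak assembly: nesting, ties, equal counts and alpha monotonicity", {
    win <- testBins[1:20]
    med <- rep(1, 20)
    cand <- rep(TRUE, 20)
    counts <- c(rep(7L, 5), rep(13L, 4), rep(14L, 6), rep(13L, 3),
                rep(7L, 2))
    mr <- fisherPeaks(win, med, cand, counts, nCarriers = 14)
    expect_length(broadPeak(mr), 1L)
    expect_length(focalPeak(mr), 1L)
    # focal peak (p < 0.01) is the count-14 run; broad adds the count-13 runs
    expect_equal(GenomicRanges::start(focalPeak(mr)),
                 GenomicRanges::start(win)[10])
    expect_equal(GenomicRanges::end(focalPeak(mr)),
                 GenomicRanges::end(win)[15])
    expect_true(GenomicRanges::start(broadPeak(mr)) <=
                GenomicRanges::start(focalPeak(mr)))
    expect_true(GenomicRanges::end(broadPeak(mr)) >=
                GenomicRanges::end(focalPeak(mr)))

    # all counts equal the baseline: every p = 1, no peaks
    mrEq <- fisherPeaks(win, med, cand, rep(5L, 20), 14)
    expect_equal(windowStats(mrEq)$fisherP[cand], rep(1, sum(cand)),
                 tolerance = 1e-12)
    expect_length(broadPeak(mrEq), 0L)
    expect_match(mrEq@diagnostic, "equal|significant")

    # raising alpha never shrinks a peak
    widths <- vapply(c(0.01, 0.05, 0.2), function(a) {
        m <- fisherPeaks(win, med, cand, counts, 14, alphaBroad = a,
                         alphaFocal = a / 5)
        if (length(broadPeak(m))) GenomicRanges::width(broadPeak(m)) else 0
    }, numeric(1))
    expect_true(all(diff(widths) >= 0))
})

test_that("focal peak stays inside the broad peak over random configurations", {
    set.seed(77)
    win <- testBins[1:30]
    for (r in 1:50) {
        counts <- as.integer(pmin(14, pmax(0, round(
            14 * exp(-abs(seq(-3, 3, length.out = 30))) + rnorm(30, 0, 2)))))
        cand <- runif(30) < 0.8
        if (!any(cand)) next
        mr <- fisherPeaks(win, rep(1, 30), cand, counts, 14)
        if (length(focalPeak(mr))) {
            expect_length(broadPeak(mr), 1L)
            expect_true(GenomicRanges::start(broadPeak(mr)) <=
                        GenomicRanges::start(focalPeak(mr)))
            expect_true(GenomicRanges::end(broadPeak(mr)) >=
                        GenomicRanges::end(focalPeak(mr)))
        }
    }
})

test_that("a shared amplified core is recovered from constructed carriers", {
    # 14 carriers whose event edges walk outward one window per carrier,
    # so every overlap count from 14 down to 2 occurs in some window
    set.seed(55)
    coreWin <- 81:90    # windows of tchr1
    profs <- list(); evs <- list()
    for (i in 1:14) {
        lo <- coreWin[1] - ((i - 1) %% 13)
        hi <- coreWin[10] + ((14 - i) %% 13)
        v <- rep(0, nWin); v[lo:hi] <- 1.4
        profs[[i]] <- profileWith(v + rnorm(nWin, 0, 0.1), paste0("c", i))
        evs[[i]] <- GenomicRanges::GRanges(
            "tchr1", IRanges::IRanges((lo - 1) * 50e3 + 1, hi * 50e3),
            sampleId = paste0("c", i))
    }
    mr <- minimalAmplifiedRegion(profs, do.call(c, evs), "tchr1")
    expect_length(focalPeak(mr), 1L)
    core <- GenomicRanges::GRanges(
        "tchr1", IRanges::IRanges((coreWin[1] - 1) * 50e3 + 1,
                                  coreWin[10] * 50e3))
    expect_gte(jaccardRegions(focalPeak(mr), core), 0.5)
    expect_true(GenomicRanges::start(broadPeak(mr)) <=
                GenomicRanges::start(focalPeak(mr)))
})
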