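# Synthetic cfDNA generator: bin tiling, the tumor/normal mixture
# expectation, cohort construction and TSS footprints.

test_that("makeBins tiles chromosomes exactly", {
    b <- makeBins(c(chrA = 150e3), binSize = 50e3)
    expect_length(b, 3L)
    expect_equal(GenomicRanges::width(b), rep(50e3, 3))

    b <- makeBins(c(chrA = 120e3), binSize = 50e3)
    expect_equal(GenomicRanges::width(b), c(50e3, 50e3, 20e3))

    b13 <- makeBins(hg19ChromLengths()["chr13"])
    expect_length(b13, 2304L)

    expect_error(makeBins(c(chrA = 1e6), binSize = 0), "binSize")
    gc <- S4Vectors::mcols(testBins)$gc
    expect_true(all(gc >= 0 & gc <= 1))
    expect_false(is.unsorted(GenomicRanges::start(
        testBins[GenomicRanges::seqnames(testBins) == "tchr1"])))
})

test_that("mixture expectation follows 1 - tf + tf*cn/2 and sums to totalReads", {
    flat <- makeBins(testGenome, gc = rep(0.45, length(testBins)))
    ev <- scnaTruth("tchr1", 2e6 + 1, 3e6, 4)

    # tf = 0: truth has no effect
    s0 <- simulationSpec(tumorFraction = 0, totalReads = 1e6)
    expect_equal(expectedCounts(flat, ev, s0),
                 expectedCounts(flat, GenomicRanges::GRanges(), s0))

    # tf = 1, cn = 4: event bins get twice the weight of cn = 2 bins
    s1 <- simulationSpec(tumorFraction = 1, totalReads = 1e6)
    mu <- expectedCounts(flat, ev, s1)
    inEv <- IRanges::overlapsAny(flat, ev)
    expect_equal(unique(mu[inEv]) / unique(mu[!inEv]), 2)

    # tf = 0.5, cn = 6: relative depth 1 - 0.5 + 0.5*3 = 2.0
    s5 <- simulationSpec(tumorFraction = 0.5, totalReads = 1e6)
    mu <- expectedCounts(flat, scnaTruth("tchr1", 2e6 + 1, 3e6, 6), s5)
    expect_equal(unique(mu[inEv]) / unique(mu[!inEv]), 2)

    expect_equal(sum(expectedCounts(testBins, ev, s5)), 1e6)
    expect_error(simulationSpec(tumorFraction = 1.2), "tumorFraction")
})

test_that("raising an event's cn never decreases its expected counts", {
    spec <- simulationSpec(tumorFraction = 0.3, totalReads = 1e6)
    ev <- function(cn) scnaTruth("tchr1", 2e6 + 1, 3e6, cn)
    inEv <- IRanges::overlapsAny(testBins, ev(2))
    prev <- expectedCounts(testBins, ev(0), spec)[inEv]
    for (cn in 1:8) {
        cur <- expectedCounts(testBins, ev(cn), spec)[inEv]
        expect_true(all(cur >= prev))
        prev <- cur
    }
})

test_that("simulated profiles are seed-deterministic", {
    ev <- scnaTruth("tchr1", 2e6 + 1, 3e6, 6)
    spec <- simulationSpec(tumorFraction = 0.2, totalReads = testReads,
                           seed = 11)
    a <- simulateProfile(testBins, ev, spec)
    b <- simulateProfile(testBins, ev, spec)
    expect_identical(SummarizedExperiment::assay(a, "counts"),
                     SummarizedExperiment::assay(b, "counts"))
})

test_that("empirical mean of simulated counts matches the model expectation", {
    spec <- simulationSpec(tumorFraction = 0.3, totalReads = testReads,
                           noise = "poisson")
    ev <- scnaTruth("tchr1", 2e6 + 1, 3e6, 8)
    mu <- expectedCounts(testBins, ev, spec)
    nRep <- 200
    acc <- matrix(0, length(testBins), nRep)
    for (r in seq_len(nRep)) {
        spec$seed <- 5000 + r
        acc[, r] <- SummarizedExperiment::assay(
            simulateProfile(testBins, ev, spec), "counts")[, 1]
    }
    se <- sqrt(mu / nRep)
    dev <- abs(rowMeans(acc) - mu) / se
    expect_gte(mean(dev <= 3), 0.985)   # ~0.3% of bins may exceed 3 SE
    expect_lt(max(dev), 5)
})

test_that("cohort simulation honours core containment and determinism", {
    core <- GenomicRanges::GRanges("tchr1", IRanges::IRanges(4e6 + 1, 4.5e6))
    spec <- simulationSpec(totalReads = testReads, seed = 21)
    co <- simulateCohort(testBins, core, nCarriers = 14, nControls = 6,
                         spec = spec)
    expect_length(co$carrierIds, 14L)
    expect_length(co$controlIds, 6L)
    expect_equal(ncol(SummarizedExperiment::assay(co$counts, "counts")), 20L)
    for (tr in co$truth) {
        amp <- tr[S4Vectors::mcols(tr)$cn >= min(8)]
        expect_true(any(GenomicRanges::start(amp) <= GenomicRanges::start(core) &
                        GenomicRanges::end(amp) >= GenomicRanges::end(core)))
    }
    co2 <- simulateCohort(testBins, core, nCarriers = 14, nControls = 6,
                          spec = spec)
    expect_identical(SummarizedExperiment::assay(co$counts, "counts"),
                     SummarizedExperiment::assay(co2$counts, "counts"))
    expect_identical(co$truth, co2$truth)

    # degenerate: no jitter, event length = core length -> events == core
    co0 <- simulateCohort(testBins, core, nCarriers = 5, nControls = 6,
                          lengthRange = rep(GenomicRanges::width(core), 2),
                          jitter = 0, backgroundGain = NULL, spec = spec)
    for (tr in co0$truth) {
        expect_equal(GenomicRanges::start(tr), GenomicRanges::start(core))
        expect_equal(GenomicRanges::end(tr), GenomicRanges::end(core))
    }
    expect_error(simulateCohort(testBins,
        GenomicRanges::GRanges("tchr1", IRanges::IRanges(1, 11e6))),
        "longer|accommodate")
})

test_that("TSS footprints encode the NDR exactly", {
    # full depletion, no noise: coverage exactly 0 on [-150, +50]
    m <- simulateTSSCoverage(tssFootprintSpec(
        nGenes = c(expressed = 3, repressed = 3), depth = 5,
        ndrDepletion = 1, phasingAmplitude = 0, noiseSd = 0, seed = 1))
    pos <- tssPositions(m)
    ndr <- pos >= -150 & pos <= 50
    cls <- geneInfo(m)$class
    expect_true(all(tssCoverage(m)[cls == "expressed", ndr] == 0))

    # depth 5, depletion 0.6: mean NDR coverage exactly 2.0
    m <- simulateTSSCoverage(tssFootprintSpec(
        nGenes = c(expressed = 2, repressed = 2), depth = 5,
        ndrDepletion = 0.6, phasingAmplitude = 0, noiseSd = 0, seed = 1))
    expect_equal(mean(tssCoverage(m)[geneInfo(m)$class == "expressed", ndr]), 2)
    expect_equal(mean(tssCoverage(m)[geneInfo(m)$class == "unexpressed", ndr]), 5)

    # no depletion, no phasing: classes identical in expectation
    m0 <- simulateTSSCoverage(tssFootprintSpec(
        nGenes = c(expressed = 2, repressed = 2), depth = 5,
        ndrDepletion = 0, phasingAmplitude = 0, noiseSd = 0, seed = 1))
    expect_equal(tssCoverage(m0)[1, ], tssCoverage(m0)[3, ],
                 ignore_attr = TRUE)

    s <- tssFootprintSpec(seed = 4)
    expect_identical(tssCoverage(simulateTSSCoverage(s)),
                     tssCoverage(simulateTSSCoverage(s)))
    expect_error(tssFootprintSpec(ndrDepletion = 1.5), "ndrDepletion")
})
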