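# Shared fixtures: a small two-chromosome test genome (360 bins at 50 kb),
# read depth scaled to keep ~2000 reads/bin as on the full mini-genome,
# and a control baseline shared across tests.

testGenome <- c(tchr1 = 10e6, tchr2 = 8e6)
testBins <- makeBins(testGenome, seed = 7)
testArms <- armsFromCentromeres(testGenome)
testReads <- 2000 * length(testBins)

testBaseline <- local({
    ctl <- vapply(1:20, function(i)
        gcCorrect(simulateProfile(testBins, GenomicRanges::GRanges(),
                                  simulationSpec(totalReads = testReads,
                                                 seed = 9000 + i)))[, 1],
        numeric(length(testBins)))
    baselineFromControls(ctl)
})

# Log2Profile built directly from a vector of values (NA = masked).
log2ProfileFromValues <- function(values, bins = testBins,
                                  sampleId = "s1") {
    computeLog2(2^values, rep(1, length(bins)), bins, sampleId = sampleId)
}

# SegmentSet built directly from coordinates and mean log2 values.
segmentSetFromTable <- function(chrom, start, end, meanLog2, nBins,
                                sampleId = "s1") {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 sampleId = sampleId, meanLog2 = meanLog2,
                                 nBins = as.integer(nBins))
    methods::new("SegmentSet", segments = gr, tumorFraction = NA_real_,
                 tfFlag = "not estimated")
}

jaccardRegions <- function(a, b) {
    ii <- sum(GenomicRanges::width(suppressWarnings(
        GenomicRanges::intersect(a, b))))
    ii / (sum(GenomicRanges::width(a)) + sum(GenomicRanges::width(b)) - ii)
}

# Brute-force two-sided Fisher p from first principles (choose-based),
# independent of the dhyper-based implementation.
bruteFisherP <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
    support <- max(0, c1 - r2):min(c1, r1)
    prob <- vapply(support, function(k)
        choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
    pObs <- prob[support == a]
    sum(prob[prob <= pObs * (1 + 1e-7)])
}
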