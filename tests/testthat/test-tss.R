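# TSS footprint extraction, flank normalization, features and the
# cross-validated expression classifier.

test_that("extraction is strand-aware and zero-fills contig edges", {
    cov <- list(ctg = rep(5, 20000))
    tss <- data.frame(gene = "gA", chrom = "ctg", pos = 10000,
                      strand = "+")
    m <- extractTSSMatrix(cov, tss)
    expect_equal(unname(tssCoverage(m)[1, ]), rep(5, 6001))

    # a dip at genomic offsets [-100, +150] of a minus-strand gene flips
    # to transcriptional positions [-150, +100]
    cov$ctg[(10000 - 100):(10000 + 150)] <- 1
    tssM <- data.frame(gene = "gB", chrom = "ctg", pos = 10000,
                       strand = "-")
    m <- extractTSSMatrix(cov, tssM)
    pos <- tssPositions(m)
    expect_true(all(tssCoverage(m)[1, pos >= -150 & pos <= 100] == 1))
    expect_true(all(tssCoverage(m)[1, abs(pos) > 150] == 5))

    # opposite strands at one TSS give mirrored rows
    both <- data.frame(gene = c("gP", "gM"), chrom = "ctg",
                       pos = 10000, strand = c("+", "-"))
    m <- extractTSSMatrix(cov, both)
    expect_equal(unname(tssCoverage(m)[1, ]),
                 rev(unname(tssCoverage(m)[2, ])))

    # TSS near the contig edge: missing bases are zero-filled with warning
    nearEdge <- data.frame(gene = "gE", chrom = "ctg", pos = 1000,
                           strand = "+")
    expect_warning(mE <- extractTSSMatrix(cov, nearEdge), "filled with 0")
    expect_equal(unname(tssCoverage(mE)[1, 1:2000]), rep(0, 2000))

    # TSS outside the contig: dropped with a message
    out <- data.frame(gene = c("gA", "gX"), chrom = "ctg",
                      pos = c(10000, 99999), strand = "+")
    expect_message(mO <- extractTSSMatrix(cov, out), "dropped")
    expect_equal(geneInfo(mO)$gene, "gA")
})

test_that("flank normalization is exact and scale-invariant", {
    spec <- tssFootprintSpec(nGenes = c(expressed = 2, repressed = 2),
                             depth = 5, ndrDepletion = 0.6,
                             phasingAmplitude = 0, noiseSd = 0, seed = 1)
    m <- simulateTSSCoverage(spec)
    norm <- tssNormalize(m)
    feats <- tssFeatures(norm)
    expect_equal(feats$flankMean, rep(5, 4))
    expect_equal(feats$ndr[geneInfo(norm)$class == "expressed"],
                 rep(0.4, 2))   # 2.0 / 5.0
    expect_equal(feats$ndr[geneInfo(norm)$class == "unexpressed"],
                 rep(1, 2))

    # doubling coverage changes no feature
    m2 <- m
    m2@coverage <- m@coverage * 2
    feats2 <- tssFeatures(tssNormalize(m2))
    expect_equal(feats2$tss2k, feats$tss2k)
    expect_equal(feats2$ndr, feats$ndr)

    # zero-coverage gene is excluded with reason
    m3 <- m
    m3@coverage[2, ] <- 0
    norm3 <- tssNormalize(m3)
    expect_equal(attr(norm3, "excluded"), geneInfo(m)$gene[2])
    expect_equal(nrow(tssCoverage(norm3)), 3L)
})

simFeatures <- function(spec) {
    m <- simulateTSSCoverage(spec)
    list(features = tssFeatures(tssNormalize(m)), info = geneInfo(m))
}

trainingFrom <- function(info, nPerClass) {
    genes <- c(info$gene[info$class == "expressed"][seq_len(nPerClass)],
               info$gene[info$class == "unexpressed"][seq_len(nPerClass)])
    stats::setNames(info$class[match(genes, info$gene)], genes)
}

test_that("well-separated classes are classified with full consistency", {
    sf <- simFeatures(tssFootprintSpec(
        nGenes = c(expressed = 60, repressed = 60), ndrDepletion = 0.7,
        noiseSd = 0.2, seed = 3))
    calls <- classifyExpression(sf$features, trainingFrom(sf$info, 40),
                                seed = 5)
    truth <- sf$info$class[match(calls$gene, sf$info$gene)]
    expect_true(all(calls$call == truth))
    expect_true(all(calls$consistency == 1))
})

test_that("every non-inconclusive call exceeds the consistency threshold", {
    sf <- simFeatures(tssFootprintSpec(
        nGenes = c(expressed = 60, repressed = 60), ndrDepletion = 0.15,
        noiseSd = 1.5, seed = 8))
    calls <- classifyExpression(sf$features, trainingFrom(sf$info, 40),
                                seed = 9)
    decided <- calls$call != "inconclusive"
    expect_true(all(calls$consistency[decided] > 0.95))
    expect_true(any(decided) || all(calls$call == "inconclusive"))
})

test_that("without signal the classifier stays at chance", {
    correct <- 0L; decided <- 0L
    for (s in 1:5) {
        sf <- simFeatures(tssFootprintSpec(
            nGenes = c(expressed = 120, repressed = 120), ndrDepletion = 0,
            phasingAmplitude = 0, noiseSd = 0.5, seed = 100 + s))
        calls <- classifyExpression(sf$features, trainingFrom(sf$info, 80),
                                    seed = 200 + s)
        truth <- sf$info$class[match(calls$gene, sf$info$gene)]
        d <- calls$call != "inconclusive"
        decided <- decided + sum(d)
        correct <- correct + sum(calls$call[d] == truth[d])
    }
    if (decided > 0) {
        acc <- correct / decided
        expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / decided) + 1e-9)
    }
    succeed()
})

test_that("fold assignment and calls are seed-deterministic", {
    sf <- simFeatures(tssFootprintSpec(
        nGenes = c(expressed = 60, repressed = 60), seed = 12))
    tr <- trainingFrom(sf$info, 40)
    a <- classifyExpression(sf$features, tr, seed = 33)
    b <- classifyExpression(sf$features, tr, seed = 33)
    expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("classifier demands complete training classes and finite features", {
    sf <- simFeatures(tssFootprintSpec(
        nGenes = c(expressed = 30, repressed = 30), seed = 2))
    few <- trainingFrom(sf$info, 10)
    expect_error(classifyExpression(sf$features, few, seed = 1),
                 "training set incomplete")
})

test_that("amplicon report covers called, missing and excluded genes", {
    empty <- reportAmpliconExpression(
        S4Vectors::DataFrame(gene = "g1", call = "expressed",
                             consistency = 1), character())
    expect_equal(nrow(empty), 0L)

    calls <- S4Vectors::DataFrame(gene = c("POLR1Dlike", "LNX2like"),
                                  call = c("expressed", "unexpressed"),
                                  consistency = c(1, 1))
    rep <- reportAmpliconExpression(
        calls, c("POLR1Dlike", "FLT3like", "ZEROG"),
        excluded = "ZEROG")
    expect_equal(rep$call,
                 c("expressed", "not evaluated",
                   "not evaluated (zero flank)"))
    expect_true(is.na(rep$consistency[2]))
})
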