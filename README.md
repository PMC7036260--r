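# cfdnaFocalScan

Copy-number analysis of shallow whole-genome sequencing of plasma
cell-free DNA (cfDNA), built around the discovery and tracking of
recurrent focal amplifications. The package takes binned genome read
counts (50-kb windows) through GC correction, baseline normalization,
log2-ratio segmentation, restrictive focal-amplification calling, cohort
recurrence statistics, delineation of the minimal common amplified
region, tumor-fraction estimation, and inference of expressed versus
unexpressed genes from nucleosome footprints around transcription start
sites (TSS) in deep plasma WGS. A synthetic-data generator with known
truth makes every stage testable end to end.

## The model in brief

Observed relative depth at a locus with tumor copy number `c` in a plasma
sample of tumor fraction `t` follows the two-component mixture

    r(c, t) = 1 - t + t * c / 2,        log2 ratio = log2 r(c, t)

Focal amplifications are segments that are short (≤ 20 Mb and ≤ 25% of
their chromosome arm) and high (mean log2 ≥ 0.2). For a cohort of
carriers, the minimal common amplified region is delineated by testing
candidate windows (median carrier log2 > 0.55) against the
lowest-frequency candidate window with a two-sided Fisher exact test:
the broad peak is the longest run of windows with p < 0.05, the focal
peak the nested run with p < 0.01. Gene expression inside an amplicon is
inferred from flank-normalized TSS coverage via two features — mean
coverage over −1000..+1000 (2K-TSS) and over −150..+50 (the
nucleosome-depleted region) — with a per-sample, cross-validated linear
SVM that only calls genes predicted identically in > 95% of folds.

## Worked example

Simulate a plasma sample carrying a 1-Mb amplicon (copy number 10) at
tumor fraction 0.15 on the bundled mini-genome, profile it against a
simulated control panel, and call focal events:

```r
library(cfdnaFocalScan)

bins  <- makeBins(miniGenome(), seed = 42)          # 2600 50-kb bins
truth <- scnaTruth("cfs1", 20e6 + 1, 21e6, cn = 10)
bc    <- simulateProfile(bins, truth,
                         simulationSpec(tumorFraction = 0.15, seed = 7))

ctl <- vapply(1:20, function(i)
    gcCorrect(simulateProfile(bins, GenomicRanges::GRanges(),
                              simulationSpec(seed = 100 + i)))[, 1],
    numeric(length(bins)))
baseline <- baselineFromControls(ctl)

prof <- computeLog2(gcCorrect(bc)[, 1], baseline, bins)
segs <- segmentProfile(prof, seed = 3)
segs <- estimateTumorFraction(segs)
segs
#> SegmentSet with 5 segments for sample sample1
#>   tumor fraction: 0.165 (ambiguous)

ev <- callFocalEvents(segs, armsFromCentromeres(miniGenome()))
ev
#> GRanges object with 1 range and 5 metadata columns:
#>       seqnames            ranges strand |    sampleId  meanLog2     nBins
#>   [1]     cfs1 20000001-21000000      * |     sample1  0.579295        20
#>              cn         arm
#>   [1]         8       cfs1p
```

The called event recovers the spiked amplicon's coordinates exactly. Its
mean log2 of 0.58 sits one noise standard error below the mixture
prediction log2(1 − 0.15 + 0.15·5) = 0.678 (per-bin log2 noise is ≈ 0.32
at this depth, so a 20-bin mean has standard error ≈ 0.07), and inverting
the mixture gives `cnFromLog2(0.579, tumorFraction(segs))` ≈ 8.0, the
integer copy number assigned to the segment. The `ambiguous` flag is the
estimator being frank: with a single altered segment, several (tf, cn)
pairs fit the mixture equally well, so it reports the smallest tied
tumor fraction — the vignette discusses when tumor fraction is
identifiable. Cohort-level statistics follow the same pattern:

```r
compareFrequencies(13, 150, 28, 619)
#> 2x2 chi-square (no continuity correction)
#>      [,1] [,2]
#> [1,]   13  137
#> [2,]   28  591
#> chi2 = 4.107, df = 1, p = 0.04272
#> frequencies: 8.7% vs 4.5%
```

`runPipeline(runConfig(list(seed = 1, outDir = "out")))` chains the whole
analysis (cohort simulation → profiles → focal events → minimal region →
tumor fractions) and writes BED/TSV/JSON artifacts; a thin CLI wrapper
lives at `inst/scripts/cfdna-focalscan`.

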