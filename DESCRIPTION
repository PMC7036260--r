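Package: cfdnaFocalScan
Title: Focal Amplicon Discovery and Tracking from Shallow Cell-Free DNA
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Copy-number analysis of shallow whole-genome sequencing of
    plasma cell-free DNA: GC-corrected, baseline-normalized log2 ratio
    profiles in fixed 50-kb genome windows, permutation-tested recursive
    binary segmentation, a restrictive focal-amplification caller with
    cohort recurrence tables, delineation of the minimal common amplified
    region by Fisher-exact broad and focal peaks over candidate windows,
    tumor-fraction estimation under a two-component tumor/normal mixture,
    inference of expressed versus unexpressed genes from nucleosome
    footprints around transcription start sites, and contingency statistics
    for cohort comparisons. Includes a synthetic-data generator that
    simulates binned cfDNA coverage with GC bias and overdispersed counts,
    patient cohorts carrying jittered focal amplicons over a shared core,
    and TSS coverage footprints, so the whole pipeline can be exercised
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
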