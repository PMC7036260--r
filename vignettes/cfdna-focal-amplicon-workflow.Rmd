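---
title: "Detecting and delineating focal amplicons in shallow cfDNA sequencing"
author: "cfdnaFocalScan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and delineating focal amplicons in shallow cfDNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdnaFocalScan)
library(GenomicRanges)
```

## The problem

Shallow whole-genome sequencing of plasma cell-free DNA (5–10 million
reads, roughly 0.1–0.2× coverage) is enough to read out somatic
copy-number alterations of a tumor from a blood draw, because the
tumor-derived fraction of cfDNA shifts the read depth of gained and lost
regions. `cfdnaFocalScan` implements the full analysis chain used to
discover, delineate and track a recurrent focal amplification in such
data:

1. **Profiling** — read counts in fixed 50-kb genome windows are
   GC-corrected, normalized against a panel of control profiles, and
   expressed as per-bin log2 ratios.
2. **Segmentation** — recursive circular binary segmentation with a
   permutation test cuts the profile into piecewise-constant segments.
3. **Focal calling** — a restrictive focal-amplification definition
   (short, high-amplitude segments) is applied per sample and aggregated
   into cohort recurrence tables.
4. **Minimal region** — carriers of a recurrent amplicon are combined to
   delineate the minimal common amplified region as nested Fisher-exact
   "broad" and "focal" peaks over candidate windows.
5. **Tumor fraction and absolute copy number** — a two-component
   tumor/normal mixture links observed log2 ratios to absolute copy
   numbers.
6. **Expression inference** — in deep (~5×) plasma WGS, the nucleosome
   footprint around transcription start sites distinguishes expressed
   from unexpressed genes inside an amplicon.
7. **Cohort statistics** — copy-number categorization and 2×2
   chi-square comparisons between cohorts.

Everything runs against a synthetic-data generator with known truth, so
every stage is testable without access to patient data.

## The mixture model

A plasma sample is modelled as a mixture of a tumor-cell population with
absolute copy number $c$ at a locus and normal cells at ploidy 2. With
tumor fraction $t$ the expected relative depth is

$$ r(c, t) = 1 - t + t\,\frac{c}{2}, $$

so the expected log2 ratio of a segment is $\log_2 r(c, t)$
(`log2FromCn()`), and conversely
$c = \bigl(2\cdot 2^{\ell} - 2(1 - t)\bigr)/t$ for an observed mean log2
ratio $\ell$ (`cnFromLog2()`); the two maps are exact inverses, which the
test suite asserts. `estimateTumorFraction()` scans $t$ over
$[0.05, 1]$ in steps of 0.005 and picks the value minimizing the
bin-weighted squared distance between segment means and the nearest model
value over integer copy numbers 0–8 — a deliberately transparent
estimator, not a probabilistic joint caller.

A caveat worth knowing: a *single* altered segment does not identify $t$.
If one segment sits at relative depth 1.4, then $t=0.4$ with $c=4$,
$t=0.2$ with $c=6$ and $t=0.8$ with $c=3$ all fit exactly. The estimator
therefore returns the smallest tied $t$ and flags the estimate
`"ambiguous"`. Profiles with several segments at different copy numbers —
in particular odd ones, or ones that would need $c > 8$ under a halved
tumor fraction — are identifiable, and the tests use such truths (copy
numbers 1, 3 and 6).

## The synthetic generator

The generator is a first-class module, not a test fixture. It simulates
at the level the analysis consumes: binned counts and per-base TSS
coverage.

* **Binned profiles** (`simulateProfile()`): expected counts follow the
  mixture above, modulated by a unimodal quadratic GC-bias curve peaking
  at GC 0.45 with range [0.7, 1] and normalized so expected counts sum to
  the library size (default 5 × 10^6 reads, the lower end of the
  instrument setting the pipeline targets). Counts are drawn negative
  binomial with dispersion 0.05 — shallow-WGS bin counts are visibly
  overdispersed relative to Poisson — giving a per-bin log2-ratio noise
  of ≈ 0.32 at ~1900 reads/bin. Poisson and noiseless modes exist for
  oracle tests.
* **Genome model**: a three-chromosome mini-genome (60/40/30 Mb, 2600
  bins at 50 kb) keeps simulations fast while preserving realistic
  geometry (a 1-Mb amplicon is ~1.5% of bins, as on a real genome);
  hg19 chromosome lengths and an approximate arm table are bundled for
  full-scale runs. GC per bin is a smooth seeded landscape in
  [0.32, 0.58].
* **Cohorts** (`simulateCohort()`): 14 carriers and a set of controls by
  default. Each carrier gets one focal amplification containing a shared
  core region, with event length uniform in 1–3 Mb, boundary jitter up to
  1.5 Mb, copy number uniform in 8–12 and tumor fraction uniform in
  0.2–0.6. Carriers additionally carry a whole-chromosome background gain
  (copy number 3) with probability 0.7. These defaults mirror the
  clinical situation the method addresses: reliable SCNA calling needs
  tumor fractions above ~0.1–0.2; recurrent amplicons that define a
  minimal region fall in the "amplification" category (copy number > 6);
  and real amplicon carriers usually show the focal spike on top of a
  broad chromosomal gain. The background gain also matters
  methodologically — it is what makes windows *outside* the shared core
  pass the median-log2 candidacy filter with low focal-event counts,
  giving the Fisher test a baseline to work against, exactly as in real
  carrier profiles.
* **TSS footprints** (`simulateTSSCoverage()`): expressed genes show a
  multiplicative nucleosome-depleted dip (default depletion 0.5) over
  positions −150..+50 relative to the TSS plus a cosine nucleosome
  phasing (period 190 bp, amplitude 0.1 × depth) outside the NDR;
  repressed genes are flat. Per-base Gaussian noise (sd 0.5) on a mean
  depth of 5 matches a ~5× deep WGS run.

What the generator does **not** emulate: fragment-level effects (sizes,
ends), mappability holes, replication-timing waves, subclonal mixtures,
and focal deletions co-occurring with amplicons. Passing tests therefore
demonstrate the correctness and calibration of the algorithms under a
clean noise model, not performance on real libraries.

## Segmentation: algorithm and numerical choices

Per chromosome, the segmenter repeatedly searches the current segment for
the *arc* (sub-interval) whose mean differs most from the rest, measured
by a two-sample t-like statistic scanned over all arc placements with at
least `minBins` (default 5) bins on each side. Using the centred
partial-sum bridge $Z_k$, the statistic for arc $(i, j]$ is
$|Z_j - Z_i|\sqrt{n/(m(n-m))}/s$ with $m = j - i$, so each scan is a
lag-loop over vectorized differences.

Significance of an accepted arc is decided hybrid-fashion: if the
conservative Bonferroni bound over all arc placements
($n^2\,\Phi(-T_{\mathrm{obs}})$) is below $\alpha/100$ the split is
accepted outright; otherwise up to `nPerm` (default 1000) seeded
permutations are run, stopping as soon as the exceedance count proves
$p \ge \alpha$ (default $\alpha = 0.01$). The permutation stream is
consumed in a fixed order, so a fixed seed reproduces the segmentation
exactly.

Two cleanup passes follow: breakpoints are locally re-optimized (each one
re-placed at the best single split between its neighbours, iterated to a
fixed point), and adjacent segments whose means differ by fewer than
`undoSD = 3` robust standard errors are re-merged — without this, noise
occasionally fragments a true amplicon into two adjacent pieces.
Segments shorter than `minBins` are merged into the neighbour with the
closer mean. Masked bins (unmappable, GC outside [0.3, 0.6], baseline or
sample depth under the 10^-3 pseudo-depth floor) are skipped entirely.

Boundary precision has a noise floor worth stating: at tumor fraction
0.15 and copy number 10 the amplicon step is log2(1.6) ≈ 0.68 against
per-bin noise ≈ 0.33, and even an oracle change-point estimator places a
boundary within ±2 bins only ~94% of the time per edge (~88% for both
edges). The pipeline's observed behaviour — every spiked amplicon
recovered, median boundary error 1 bin, ~85–90% of runs with both edges
within 2 bins — sits at that statistical ceiling.

## GC correction and baseline

`gcCorrect()` fits the count-versus-GC trend with *robust* loess
(`family = "symmetric"`, span 0.75, quadratic): a plain least-squares
trend gets dragged by amplified bins and eats part of the very signal the
pipeline is after. A median-per-GC-decile fallback is available.
Corrected depths are rescaled to mean 1 over unmasked bins. The baseline
is the per-bin median of at least five GC-corrected control profiles;
the worked examples use 20 controls, which noticeably stabilizes window
medians compared to the minimum panel.

## Minimal-region procedure

For the carriers of a recurrent amplicon, per-window medians of the
carrier log2 ratios are computed on the target chromosome (even-count
median = mean of the central pair; a window's median is reported when at
least half the carriers are unmasked there). Windows with median > 0.55
are *candidates*. For each candidate window the number of distinct
carriers whose focal event overlaps it (≥ 1 bp) is counted; the minimum
count among candidates serves as the baseline $m$, and each candidate
window is tested against it with a two-sided Fisher exact test on
$[[k_w, n - k_w], [m, n - m]]$. The broad peak is the longest contiguous
run of windows with $p < 0.05$ (ties leftmost), the focal peak the
longest contiguous sub-run with $p < 0.01$; single non-significant
windows are not bridged. Raw (uncorrected) thresholds are used by
design — the procedure reports nested significance tiers, not a
multiplicity-adjusted discovery set.

One guard is applied before testing: candidate windows must form runs of
at least `minCandidateRun = 3` consecutive windows. Without it, a single
noise window far from the amplicon — easily produced when carriers have a
broad chromosomal gain sitting just under the 0.55 threshold — can enter
the candidate set with an event count of zero, drag the baseline $m$ to
zero, and degenerate the procedure into calling the whole candidate run
"focal". A real amplicon's candidate region always spans many
consecutive windows, so the filter only removes noise.

With 14 carriers the exact test has a hard floor: a window covered by all
14 carriers reaches $p < 0.01$ against a baseline of $m \le 7$
(p = 0.0058 at $m = 7$) but not against $m = 8$ (p = 0.016). Whether a
candidate window with count ≤ 7 exists is a property of the cohort's
event geometry; the background-gain default of the generator makes such
windows reliably candidate, which is also how the real data behave.

## TSS expression inference

Coverage in ±3 kb windows around TSSs (strand-oriented) is normalized by
each gene's flank mean (−3000..−1000 and +1000..+3000); two scalar
features follow — mean normalized coverage over −1000..+1000 ("2K-TSS")
and over −150..+50 ("NDR"). Classification is strictly within-sample: the
constitutively expressed/unexpressed training genes are split into
k = 10 class-stratified seeded folds; per fold a linear SVM is fit on the
other folds (feature scaling learned on those folds only, guarding
against leakage) and applied to all non-training genes. A gene is called
only when more than 95% of folds agree — with k = 10 that means
unanimity — otherwise it is `inconclusive`. The linear kernel is the
right default for two features and small training sets; an RBF kernel is
one argument away. Normalization makes calls invariant to rescaling the
sample's coverage, and at zero NDR depletion with no phasing the
classifier stays at chance — both asserted in the tests.

The full normalized profile (rather than the two features) is a
plausible alternative input; the two-feature reading is implemented
because it is the one the feature definitions support directly.

## Copy-number categories and cohort statistics

Absolute copy numbers are categorized with half-open intervals: loss
(cn ≤ 1), balanced (1 < cn ≤ 3), gain (3 < cn ≤ 6), amplification
(cn > 6); so cn = 3 is balanced and cn = 6 is gain. Cohort frequency
comparisons build a 2×2 table and use Pearson's chi-square *without*
continuity correction by default — the reconstructed 13/150-vs-28/619
carrier table reproduces the published p = 0.043 only without Yates
correction; the corrected variant is available via a flag. Percentages
are printed half-up to one decimal.

## Problem sizes used in the checks

The shipped tests and the acceptance script run, per invocation: 50
spike-in simulations and 20 cohort simulations of 14 carriers + 20
controls on the 2600-bin mini-genome; 10 + 10 TSS simulations with 600
genes each; the full Fisher-oracle enumeration up to 20 carriers; and
500-draw round-trip property checks. These sizes make the whole suite
run in minutes while keeping the Monte-Carlo error of the asserted rates
small relative to their margins.

## Known limitations

* The tumor-fraction estimator is a least-squares grid search, not a
  joint probabilistic model; near-neutral profiles below |log2| ≈ 0.05
  are flagged rather than estimated, and single-segment profiles are
  inherently ambiguous.
* Focal deletion calling mirrors the gain rules but is not exercised by
  a dedicated recovery study.
* The bundled hg19 arm table uses approximate centromere midpoints;
  supply an exact cytoband-derived table for production use.
* The restrictive focal-event thresholds (20 Mb, 25% of arm,
  log2 ≥ 0.2) are this package's documented defaults; they are exposed
  in `focalParams()` precisely because the field has no single agreed
  definition.
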