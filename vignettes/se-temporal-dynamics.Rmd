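---
title: "Classifying the temporal dynamics of super-enhancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the temporal dynamics of super-enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sedyn` classifies super-enhancers (SEs) by how their H3K27ac signal
evolves across an ordered differentiation time course. This vignette is
the package's account of the method: the model and its assumptions, the
parameters that matter, the numerical choices made where the procedure
is genuinely open, what the synthetic generator does and does not
emulate, and the package's known limitations.

## The data model

The pipeline assumes:

- an ordered set of T stages (T ≥ 3; the default generator uses T = 5);
- per-stage peak sets in BED half-open coordinates, already called and
  blacklist-filtered upstream (peak calling is out of scope; a
  `filter_blacklist()` helper is provided for the standard any-overlap
  removal);
- per-peak, per-stage read counts and per-stage library sizes, from
  which signal is expressed as reads per million mapped reads (RPM).
  RPM is a pure library-size scaling — no peak-length normalization —
  because counts are confined to peaks of comparable width and the
  downstream vectors are max-normalized per SE anyway;
- optionally: a gene-by-stage RPKM matrix with TSS annotation, and
  per-stage cis contact matrices plus PC1 compartment tracks.

Peaks from all stages are merged into a unified set (overlapping or
bookended intervals merge, `bedtools merge -d 0` semantics, via
`GenomicRanges::reduce`); a unified peak belongs to a stage when any of
that stage's peaks overlaps it by at least 1 bp. Quantile normalization
across stages (`limma::normalizeQuantiles`, ties averaged over the tied
rank span) removes stage-to-stage signal-to-noise differences at the
cost of a known artifact discussed under Limitations.

## SE calling

Stage-present unified peaks are stitched within `stitch_distance`
(default 12 500 bp, the conventional ROSE value) and regions are ranked
by total constituent RPM at the calling stage. The cutoff is geometric:
with rank and signal each min–max scaled to [0, 1], it is the curve
point farthest below the unit-slope diagonal — equivalently the point
where a slope-1 line supports the curve from below, the tangent of the
familiar hockey-stick plot. We compute this support point directly
rather than scanning a finite-difference slope for its first crossing
of 1: on stepped or noisy rank curves the discrete slope is not
monotone, so a slope-scan depends on the discretization stencil, while
the support point is unique and is exactly what the tangent
construction defines. The test suite verifies agreement with an
exhaustive line-versus-every-point oracle on random instances up to
n = 200. Regions strictly above the cutoff signal are SEs; ties at the
cutoff are excluded, and a degenerate all-equal input calls zero SEs
with a warning.

SEs whose promoter-peak fraction is ≥ `promoter_fraction_max` (default
0.5) are removed; a constituent is a promoter peak only when fully
contained in TSS ± `tss_window` (default 2 000 bp, closed endpoints in
genomic bp). Under the default rule an SE with 3 or 4 constituents may
keep at most one promoter peak. Stitching applies no TSS exclusion: the
explicit promoter-fraction filter is the promoter control, and adding a
second, implicit one would double-count the same concern.

## Fixed-length temporal vectors

SEs have different numbers of constituents, so their raw submatrices
(constituents × stages) cannot be clustered directly. Each SE is
standardized to `n_representatives` (default 4) series:

1. constituents are sorted ascending by relative standard deviation
   (RSD = population sd / mean across stages; all-zero profiles get
   RSD 0; ties break lexicographically by constituent id for
   determinism);
2. for every stage, the signal profile along the sorted axis is
   linearly interpolated at fractions {0, 1/3, 2/3, 1} of the axis;
3. the four interpolated series are concatenated
   representative-major into one 4 × T vector, then divided by its
   maximum (`normalize = TRUE`, mirroring relative-signal heatmaps;
   switchable off).

"Percentiles per time point" admits a second reading — independent
order statistics of each stage's values. We interpolate along the
single RSD-sorted axis because the documented RSD sort would otherwise
have no effect on the result; the alternative is available as
`per_stage_sorted = TRUE` for comparison. With exactly 4 constituents
the representatives equal the sorted constituent profiles verbatim; a
single-constituent SE repeats its profile four times.

## Consensus clustering and labeling

`consensus_kmeans()` runs `n_rounds` (default 100) k-means
(`stats::kmeans`, Euclidean, K = 3) with per-round seeds derived
deterministically from one `master_seed`, accumulates the
co-association matrix (fraction of rounds placing two SEs together),
and cuts an average-linkage tree of 1 − co-association into K groups.
Co-association plus a tree cut is the simplest reproducible consensus
construction and sidesteps any need to match cluster labels across
rounds. Because `stats::kmeans` seeds its centers by sampling rows, the
rows are processed in a canonical lexicographic order internally and
mapped back, making the partition exactly invariant to input order.

Clusters are named by the area under their mean max-normalized
trajectory: highest → Con, middle → TH, lowest → DN. The same ordering
serves decommission analyses (reference stage = first): a rapidly
decommissioned SE loses its signal early and again has the lowest
area. Identical cluster means abort with an error; K ≠ 3 yields
neutral `cluster_<k>` names with area ranks, since the three subtype
names are only meaningful at K = 3.

Constituent timing within an SE uses an explicit commission rule,
since "commission" needs a number: an element commissions at the first
stage where its signal reaches `alpha` (default 0.5) of its own
maximum; commission at stage 0 is early, at stage ≥ T − 2 late,
otherwise intermediate; all-zero elements are flagged undefined.

## Target genes and expression metrics

A gene is a target of an SE when (i) its TSS is within `window`
(default 100 kb) of the SE edge (distance 0 inside), (ii) its maximum
RPKM across stages is ≥ `rpkm_min` (default 2) — applied to the
maximum so that a gene silent early but active late stays eligible —
and (iii) the Pearson correlation between its RPKM series and the SE's
summed quantile-normalized signal exceeds `r_min` (default 0.75).
Zero-variance genes are excluded (undefined correlation). Fold change
is last-stage over first-stage RPKM with a disclosed 0.01 pseudocount;
specificity at stage M is `sqrt(X_M^2 / sum_i X_i^2)` (scale-invariant;
its squares over stages sum to 1); gene density counts TSSs within
± 500 kb of the SE midpoint per Mb (window and unit are package
choices; no standard exists). Group differences use two-sided
Mann-Whitney U tests with the conventional star coding.

## Hi-C features

- **Insulation / TAD boundaries** (40 kb bins, 600 kb square, 200 kb
  delta): per-bin mean contact in a square sliding along the diagonal,
  log2-normalized to the chromosome mean of nonzero values; boundaries
  sit at positive-to-negative zero crossings of the left-minus-right
  delta series and are kept when the delta swing (boundary strength)
  reaches 0.5. A literal reading — thresholding the (negated)
  insulation value itself at 0.5 — is exposed as
  `method = "insulation"`, but boundary strength is the default
  because that is what the 0.5 threshold means in the insulation-score
  method this follows.
- **FIRE scores** (50 kb bins): raw score = total contacts to bins 1–4
  away (≤ 200 kb, self-diagonal excluded), normalized within sample as
  a z-score of log1p(raw) over usable (non-empty) bins and across
  samples by quantile normalization. The full FIRE machinery regresses
  out mappability/GC/fragment covariates; those require external
  genome tracks, so this package deliberately uses the simpler
  normalization — fine for comparing bins within one synthetic or
  uniformly processed genome, and stated here so nobody mistakes it
  for the covariate-adjusted score. Top 10 % of usable bins per stage
  (ceiling; ties toward low bin index) are FIREs.
- **Compartment switching**: PC1 sign pairs between first and last
  stage map to stableA/stableB/AtoB/BtoA; zero PC1 is unassigned. PC1
  itself comes from upstream tools; only the categorization is in
  scope.
- **Enrichment**: SE constituents versus boundary bins against 20
  seeded draws of 1 000 regular enhancers; SE regions versus FIRE bins
  against length-matched random regions; compartment distribution via
  a plain (uncorrected) chi-square test. Zero-fraction draws yield NA
  folds rather than pseudocounted values.

## The synthetic generator

`simulate_se_bundle()` is first-class, tested code, and defines the
study conditions for validation: 100 SEs per archetype, T = 5, 3–15
constituents per SE, multiplicative log-normal noise with CV 0.1,
active/inactive/background levels 20/0.5/3 RPM, 2 × 10^7 mapped reads
per stage. TH onsets are uniform over stages 1..T−1 with one element
forced active at stage 0 (definitional for the archetype); DN elements
all commission at T − 2. Log-normal noise was chosen because signals
are nonnegative intensities. True-target genes follow their SE's
*measured* (quantile-normalized, summed) signal perturbed by Gaussian
noise with sd equal to 0.2 × the signal's temporal sd — a population
correlation near 0.98, i.e. tightly coupled enhancer–gene pairs —
then scaled to a 10 RPKM maximum; each SE also gets two decoy genes
inside the 100 kb window whose expression is independent flat noise.
Toy Hi-C chromosomes carry block TADs (30–60 bins of 40 kb, blocks at
least twice the insulation square), 8 % of 50 kb bins with 10-fold
inflated short-range contacts, and a blocky two-sign compartment
track. `time_reverse()` flips the stage axis of every component to
produce decommission fixtures.

What the generator does **not** emulate: read-level noise and mapping
artifacts, copy-number and input-control effects, overlapping or
nested SE loci, inter-chromosomal variation in signal-to-noise,
distance-decay calibration beyond a simple power law, and genes with
multiple regulating SEs. Passing recovery tests therefore demonstrates
the correctness and stability of the computation under the stated
statistical structure, not performance on any real dataset.

Problem sizes in the tests and acceptance script — 300 SEs, ~3 300
unified peaks, toy matrices of 250/400/200 bins, 100 consensus rounds
— were chosen so the whole validation runs in about a minute while
leaving every planted structure comfortably detectable.

## Limitations

- Cross-stage quantile normalization couples stages: when late stages
  contain more active peaks, conserved SEs acquire a mild systematic
  downward trend in normalized signal (their ranks dilute). Subtype
  recovery is robust to this, but correlations of *flat* SEs with
  trending gene profiles can be inflated; the decoy design in the
  generator was chosen accordingly (independent noise, not trending
  profiles), and users correlating against raw RPM can pass the
  un-normalized matrix.
- With only T points, Pearson correlations are noisy; the r > 0.75
  threshold is meaningful for T ≥ 5 but should be treated cautiously
  for shorter courses (the package enforces T ≥ 3).
- Cutting the consensus tree at K > 3 subdivides the TH continuum
  (element onsets are a continuum, not a mixture), so finer K mostly
  refines TH rather than revealing new archetypes; K = 4 leaves each
  K = 3 cluster dominated by a single descendant on the default
  conditions, while K = 5 begins to split the TH cloud.
- The FIRE normalization is the simplified within/across-sample
  scheme described above, not the covariate-regressed score.
- The elbow cutoff assumes at least two distinct signal values; flat
  signal landscapes call no SEs by design.

```{r example}
library(sedyn)
bundle <- simulate_se_bundle(master_seed = 1)
res <- run_se_pipeline(bundle, master_seed = 1)
glance(res$classification)
autoplot(res$classification)
```
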