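# sedyn — temporal dynamics of super-enhancers

Super-enhancers (SEs) are dense clusters of enhancer elements carrying
unusually high H3K27ac signal. Most SE catalogs describe a single static
cell state; `sedyn` is for the dynamic question: *how* does an SE come
into being (or get decommissioned) across a differentiation time course?
Given per-stage H3K27ac peak sets and signals, it classifies every SE
into one of three temporal subtypes:

- **Con** (conserved): signal persistent throughout differentiation;
- **TH** (temporally hierarchical): at least one element active early,
  the rest commissioned at staggered stages;
- **DN** (de novo): all elements gain signal simultaneously at late
  stages.

The package is aimed at regulatory-genomics analysts working with
time-course ChIP-seq (plus optional RNA-seq and Hi-C) who want a tested,
reproducible implementation of the whole workflow rather than a pile of
one-off scripts.

## The method

1. **Unified peak set.** Peaks from all stages are pooled and merged
   (overlapping or bookended intervals, the `bedtools merge -d 0`
   convention); each stage's membership is recorded by ≥ 1 bp overlap.
   Per-peak signals are expressed as reads per million mapped reads
   (RPM) and quantile-normalized across stages.
2. **SE calling (ROSE-style).** Peaks present at a reference stage
   (last stage for activation, first for decommission) are stitched
   within 12.5 kb; stitched regions are ranked by total signal and the
   elbow of the min–max-scaled rank curve — the point where a slope-1
   line supports the curve from below — sets the cutoff. SEs whose
   promoter-peak fraction is ≥ 50 % are removed (a promoter peak is one
   fully contained in TSS ± 2 kb).
3. **Fixed-length SE vectors.** For each SE, constituents are sorted by
   relative standard deviation (RSD = sd/mean across stages) and the
   per-stage profile along that axis is linearly interpolated at
   fractions {0, 1/3, 2/3, 1}, yielding 4 "representative enhancers"
   and one vector of length 4 × T per SE.
4. **Consensus k-means.** 100 rounds of k-means (K = 3) with seeded
   random starts feed a co-association matrix; average-linkage
   clustering of 1 − co-association is cut into K groups, and clusters
   are named Con / TH / DN by the area under their mean max-normalized
   trajectory.
5. **Target genes and metrics.** Expressed genes (max RPKM ≥ 2) within
   100 kb of an SE whose expression correlates with the SE signal
   (Pearson r > 0.75) are its targets; per-gene fold change
   (last/first stage), expression specificity
   `sqrt(X_M^2 / sum_i X_i^2)`, and local gene density are compared
   between subtypes with Mann-Whitney U tests.
6. **Hi-C architecture (optional).** Insulation-score TAD boundaries
   (600 kb square / 200 kb delta at 40 kb bins, boundary strength
   ≥ 0.5), FIRE scores (short-range < 200 kb contacts per 50 kb bin,
   top 10 % are FIREs), A/B compartment-switch categories from PC1
   signs, and seeded enrichment of SEs at boundaries/FIREs.

A ground-truth synthetic generator (`simulate_se_bundle()`) emits all
of the above inputs with planted labels, so the full pipeline is
testable end to end.

## Worked example

```r
library(sedyn)

bundle <- simulate_se_bundle(master_seed = 1) # 300 planted SEs, T = 5
res <- run_se_pipeline(bundle, master_seed = 1)
res
#> <se_pipeline> activation analysis, seed 1
#>   3289 unified peaks -> 300 SEs (cutoff 1.73)
#>   classes: Con=102 DN=102 TH=96
#>   342 target-gene assignments

glance(res$classification)
#> # A tibble: 1 × 8
#>    n_se     k n_rounds master_seed mean_coassociation n_con  n_th  n_dn
#>   <int> <dbl>    <dbl>       <dbl>              <dbl> <int> <int> <int>
#> 1   300     3      100           1              0.992   102    96   102

res$metric_tests
#> # A tibble: 3 × 5
#>   group1 group2 statistic  p_value stars
#>   <chr>  <chr>      <dbl>    <dbl> <chr>
#> 1 Con    DN            78 3.47e-39 ***
#> 2 Con    TH           123 1.33e-36 ***
#> 3 DN     TH          8670 2.70e- 6 ***
```

The 900 stitched candidate regions yield 300 SEs above the rank-curve
cutoff (signal 1.73 RPM), split 102/96/102 into Con/TH/DN — matching
the 100/100/100 planted archetypes up to boundary cases (adjusted Rand
index 0.94 against the planted labels). The within-cluster mean
co-association of 0.992 says the 100 k-means rounds almost always
agree. Target-gene fold changes differ sharply between subtypes (DN
highest, Con lowest; all pairwise Mann-Whitney p < 0.001), mirroring
the expected coupling between SE commission and transcription.
`autoplot(res$classification)` draws the three mean trajectories;
`autoplot(res$se_call)` the SE hockey-stick curve.

For real data, build the inputs with the readers (`read_peak_bed()`,
`read_count_table()`, `read_expression_table()`, `read_tss_table()`,
`read_contact_triplets()`, `read_pc1_bedgraph()`) and pass the same
list structure to `run_se_pipeline()`; use
`reference_stage = "first"` to analyze SE decommission from the
starting cell state.

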