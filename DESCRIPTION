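Package: sedyn
Title: Temporal Dynamics of Super-Enhancers Across Differentiation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the evolving landscape of super-enhancers (SEs) across a
    cell-differentiation time course from per-stage H3K27ac ChIP-seq peak
    sets and signals. Builds a unified peak set and quantile-normalized
    reads-per-million signal matrix, calls super-enhancers with a
    ROSE-style stitching and rank-curve elbow procedure plus a
    promoter-fraction filter, standardizes each SE into a fixed-length
    temporal vector via interpolation of RSD-sorted constituents, and
    classifies SEs into conserved, temporally hierarchical, and de novo
    subtypes by consensus k-means. Also assigns target genes by distance
    and expression correlation, computes expression specificity and
    fold-change metrics, times constituent-element commission, and derives
    Hi-C architecture features (compartment switching, insulation-score
    TAD boundaries, FIRE scores) from contact matrices. Includes a
    synthetic-data generator with ground-truth labels for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
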