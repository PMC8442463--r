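#' Assign target genes to super-enhancers
#'
#' Two-step rule: (1) every expressed gene (maximum RPKM across stages >=
#' `rpkm_min`) whose TSS lies within `window` bp of the SE is a potential
#' target; (2) a potential target is kept only when the Pearson correlation
#' between its RPKM series and the SE's per-stage H3K27ac signal (sum over
#' constituents) exceeds `r_min`. Distance is measured TSS to nearest SE
#' edge (0 when the TSS falls inside the SE). Genes with zero expression
#' variance are excluded (their correlation is undefined).
#'
#' @param ses SE tibble with `se_id`, `chrom`, `start`, `end`,
#'   `constituents`.
#' @param signal A `signal_matrix` over the constituents (stage columns
#'   must match the expression stages).
#' @param expr Expression tibble: `gene_id` plus one RPKM column per stage
#'   in temporal order.
#' @param tss TSS tibble: `gene_id`, `chrom`, `tss`, `strand`.
#' @param window Maximum TSS-to-SE distance in bp (default 1e5).
#' @param rpkm_min Expression floor on the gene's max RPKM (default 2).
#' @param r_min Pearson correlation threshold, exclusive (default 0.75).
#' @return Tibble `se_id`, `gene_id`, `distance`, `correlation`, one row
#'   per passing (SE, gene) pair.
#' @export
assign_targets <- function(ses, signal, expr, tss, window = 1e5,
                           rpkm_min = 2, r_min = 0.75) {
  stages <- attr(signal, "stages")
  expr_stages <- setdiff(names(expr), "gene_id")
  if (length(expr_stages) != length(stages)) {
    abort("expression table and signal matrix have different stage sets")
  }
  if (length(stages) < 3) abort("need >= 3 stages for Pearson correlation")
  if (nrow(ses) == 0) {
    return(tibble(se_id = character(), gene_id = character(),
                  distance = double(), correlation = double()))
  }

  em <- as.matrix(expr[, expr_stages])
  rownames(em) <- expr$gene_id
  sig <- signal_values(signal)
  se_sig <- t(sapply(ses$constituents,
                     function(ids) colSums(sig[ids, , drop = FALSE])))
  rownames(se_sig) <- ses$se_id

  tss <- tss[order(tss$gene_id), ]
  pairs <- map(seq_len(nrow(ses)), function(i) {
    g <- tss[tss$chrom == ses$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    # distance from TSS to nearest SE edge, 0 inside [start, end)
    d <- pmax(0, pmax(ses$start[i] - g$tss, g$tss - (ses$end[i] - 1)))
    g <- g[d <= window, , drop = FALSE]
    d <- d[d <= window]
    if (nrow(g) == 0) return(NULL)
    tibble(se_id = ses$se_id[i], gene_id = g$gene_id, distance = d)
  })
  pairs <- bind_rows(pairs)
  if (nrow(pairs) == 0) {
    return(tibble(se_id = character(), gene_id = character(),
                  distance = double(), correlation = double()))
  }
  pairs <- pairs[pairs$gene_id %in% rownames(em), , drop = FALSE]
  keep_expr <- apply(em, 1, max) >= rpkm_min
  nonconst <- apply(em, 1, function(v) sd(v) > 0)
  pairs <- pairs[keep_expr[pairs$gene_id] & nonconst[pairs$gene_id], ,
                 drop = FALSE]
  if (nrow(pairs) == 0) {
    return(tibble(se_id = character(), gene_id = character(),
                  distance = double(), correlation = double()))
  }
  pairs$correlation <- map_dbl(seq_len(nrow(pairs)), function(j) {
    s <- se_sig[pairs$se_id[j], ]
    if (sd(s) == 0) return(NA_real_)
    cor(em[pairs$gene_id[j], ], s)
  })
  out <- pairs[!is.na(pairs$correlation) & pairs$correlation > r_min, ,
               drop = FALSE]
  arrange(as_tibble(out), .data$se_id, .data$gene_id)
}

#' Expression specificity of a gene at a focal stage
#'
#' `sqrt(X_M^2 / sum_i X_i^2)`: how exclusively a gene's expression
#' concentrates at stage M. Equals 1 when the gene is expressed only at M
#' and `1/sqrt(T)` for a uniform profile over T stages. The squared
#' specificities over all stages sum to 1.
#'
#' @param x Nonnegative per-stage expression vector (not all zero).
#' @param M Focal stage index (1-based).
#' @return Specificity in (0, 1].
#' @export
specificity <- function(x, M) {
  if (all(x == 0)) abort("specificity undefined for an all-zero profile")
  sqrt(x[M]^2 / sum(x^2))
}

#' Expression fold change over the time course
#'
#' `(x_last + pseudocount) / (x_first + pseudocount)` — last-stage over
#' first-stage expression, with a small pseudocount guarding division by
#' zero.
#'
#' @param x Per-stage expression vector in temporal order.
#' @param pseudocount Added to numerator and denominator (default 0.01
#'   RPKM).
#' @return The fold change.
#' @export
fold_change <- function(x, pseudocount = 0.01) {
  (x[length(x)] + pseudocount) / (x[1] + pseudocount)
}

#' Max-normalized expression profile
#'
#' Divides a profile by its maximum, so group averages can be compared on a
#' relative scale.
#'
#' @param x Nonnegative per-stage vector.
#' @return `x / max(x)` (all-zero input returned unchanged).
#' @export
relative_profile <- function(x) {
  m <- max(x)
  if (m == 0) return(x)
  x / m
}

#' Gene density around a super-enhancer
#'
#' Counts TSSs within +/- `window` bp of the SE midpoint and reports genes
#' per Mb.
#'
#' @param se One-row SE data frame (`chrom`, `start`, `end`) or a list with
#'   those fields.
#' @param tss TSS tibble (`chrom`, `tss`).
#' @param window Half-window in bp (default 5e5).
#' @return Genes per Mb (count / (2 * window / 1e6)).
#' @export
gene_density <- function(se, tss, window = 5e5) {
  mid <- floor((se$start + se$end) / 2)
  k <- sum(tss$chrom == se$chrom & abs(tss$tss - mid) <= window)
  k / (2 * window / 1e6)
}

#' Pairwise Mann-Whitney comparison of SE-type metric distributions
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) tests between every pair
#' of groups, with the figure-legend star coding (* < 0.05, ** < 0.01,
#' *** < 0.001).
#'
#' @param groups Named list of numeric vectors (one per SE type).
#' @return Tibble `group1`, `group2`, `statistic`, `p_value`, `stars`.
#' @export
group_compare <- function(groups) {
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  cmb <- utils::combn(seq_along(groups), 2)
  out <- map(seq_len(ncol(cmb)), function(j) {
    i1 <- cmb[1, j]; i2 <- cmb[2, j]
    wt <- suppressWarnings(
      wilcox.test(groups[[i1]], groups[[i2]], alternative = "two.sided"))
    tibble(group1 = nm[i1], group2 = nm[i2],
           statistic = unname(wt$statistic), p_value = wt$p.value,
           stars = p_stars(wt$p.value))
  })
  bind_rows(out)
}

#' Fraction of target genes found in a reference gene set
#'
#' Generic gene-set overlap, e.g. against a housekeeping-gene list.
#'
#' @param target_genes Character vector of gene ids (duplicates ignored).
#' @param reference_set Character vector of reference gene ids.
#' @return Fraction of unique target genes present in the reference set.
#' @export
geneset_overlap <- function(target_genes, reference_set) {
  tg <- unique(target_genes)
  if (length(tg) == 0) return(NA_real_)
  mean(tg %in% reference_set)
}

#' Per-subtype expression metric table
#'
#' Joins target assignments to subtype labels and computes, per target
#' gene, the fold change, final-stage specificity, and the SE's local gene
#' density.
#'
#' @param targets Target assignment tibble from [assign_targets()].
#' @param classification `se_classification` or tibble `se_id`, `label`.
#' @param expr Expression tibble (`gene_id` + stage columns).
#' @param ses SE tibble (for gene density).
#' @param tss TSS tibble.
#' @param focal_stage 1-based stage index for specificity (default last).
#' @param pseudocount Fold-change pseudocount (default 0.01).
#' @param density_window Gene-density half-window (default 5e5).
#' @return Tibble `se_id`, `label`, `gene_id`, `fold_change`,
#'   `specificity`, `gene_density`.
#' @export
se_target_metrics <- function(targets, classification, expr, ses, tss,
                              focal_stage = NULL, pseudocount = 0.01,
                              density_window = 5e5) {
  if (inherits(classification, "se_classification")) {
    classification <- classification$classification
  }
  stages <- setdiff(names(expr), "gene_id")
  focal_stage <- focal_stage %||% length(stages)
  em <- as.matrix(expr[, stages])
  rownames(em) <- expr$gene_id
  dens <- map_dbl(seq_len(nrow(ses)),
                  function(i) gene_density(ses[i, ], tss,
                                           window = density_window))
  names(dens) <- ses$se_id
  targets |>
    inner_join(classification[, c("se_id", "label")], by = "se_id") |>
    mutate(
      fold_change = map_dbl(.data$gene_id,
                            function(g) fold_change(em[g, ], pseudocount)),
      specificity = map_dbl(.data$gene_id,
                            function(g) specificity(em[g, ], focal_stage)),
      gene_density = unname(dens[.data$se_id])
    ) |>
    select("se_id", "label", "gene_id", "fold_change", "specificity",
           "gene_density")
}
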