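#' Construct a cis contact matrix
#'
#' Builds a dense symmetric contact matrix for one chromosome from triplet
#' records (0-based bin indices at a fixed resolution). Input triplets may
#' cover either or both triangles; the matrix is symmetrized by taking the
#' maximum of the two mirror entries, so symmetric storage order does not
#' matter.
#'
#' @param triplets Data frame `chrom`, `bin_i`, `bin_j`, `count`
#'   (`count >= 0`).
#' @param resolution Bin size in bp.
#' @param n_bins Number of bins; defaults to `max(bin) + 1`.
#' @return A list of class `"contact_matrix"`: `chrom`, `resolution`,
#'   `n_bins`, `mat` (dense symmetric matrix).
#' @export
contact_matrix <- function(triplets, resolution, n_bins = NULL) {
  if (any(triplets$count < 0)) abort("contact counts must be >= 0")
  n_bins <- n_bins %||% (max(triplets$bin_i, triplets$bin_j) + 1L)
  if (any(triplets$bin_i >= n_bins | triplets$bin_j >= n_bins)) {
    abort("bin index exceeds n_bins")
  }
  m <- matrix(0, n_bins, n_bins)
  m[cbind(triplets$bin_i + 1L, triplets$bin_j + 1L)] <- triplets$count
  m <- pmax(m, t(m))
  structure(list(chrom = as.character(triplets$chrom[1]),
                 resolution = as.integer(resolution),
                 n_bins = as.integer(n_bins), mat = m),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins at %d bp\n",
              x$chrom, x$n_bins, x$resolution))
  invisible(x)
}

#' Categorize compartment switching between first and last stage
#'
#' Classifies each bin by the signs of the PC1 compartment eigenvector at
#' the first and last differentiation stage: `(+,+)` stableA, `(-,-)`
#' stableB, `(+,-)` AtoB, `(-,+)` BtoA; a zero PC1 at either stage leaves
#' the bin unassigned.
#'
#' @param pc1_first,pc1_last Tibbles `chrom`, `start`, `end`, `pc1` on the
#'   same binning.
#' @return Tibble `chrom`, `start`, `end`, `pc1_first`, `pc1_last`,
#'   `category`.
#' @export
categorize_compartments <- function(pc1_first, pc1_last) {
  same <- nrow(pc1_first) == nrow(pc1_last) &&
    all(pc1_first$chrom == pc1_last$chrom) &&
    all(pc1_first$start == pc1_last$start) &&
    all(pc1_first$end == pc1_last$end)
  if (!same) abort("PC1 tracks are on different binnings")
  a <- pc1_first$pc1
  b <- pc1_last$pc1
  category <- dplyr::case_when(
    a == 0 | b == 0 ~ "unassigned",
    a > 0 & b > 0 ~ "stableA",
    a < 0 & b < 0 ~ "stableB",
    a > 0 & b < 0 ~ "AtoB",
    TRUE ~ "BtoA"
  )
  tibble(chrom = pc1_first$chrom, start = pc1_first$start,
         end = pc1_first$end, pc1_first = a, pc1_last = b,
         category = category)
}

#' Insulation-score profile and TAD boundaries
#'
#' Crane-style insulation: for each bin, the mean contact signal in a
#' square of side `square` bp sliding along the diagonal (upstream bins x
#' downstream bins across the focal bin), log2-normalized to the
#' chromosome mean of nonzero insulation values. A delta series contrasts
#' the mean normalized insulation of the left and right flanks of width
#' `delta` bp; TAD boundaries are the insulation minima at
#' positive-to-negative zero crossings of delta, kept when the boundary
#' strength (left delta maximum minus right delta minimum across the
#' crossing) reaches `threshold`.
#'
#' `method = "insulation"` instead applies the literal reading in which
#' bins whose boundary signal (negated normalized insulation) is
#' >= `threshold` are boundaries.
#'
#' @param cm A `contact_matrix` (typically at 40 kb resolution).
#' @param square Insulation square size in bp (default 6e5).
#' @param delta Delta flank size in bp (default 2e5).
#' @param threshold Boundary-strength threshold (default 0.5).
#' @param method `"strength"` (default, Crane boundary strength) or
#'   `"insulation"`.
#' @return A list of class `"insulation_profile"`: `profile` (tibble `bin`
#'   0-based, `start`, `end`, `insulation` raw mean, `score` log2 ratio,
#'   `delta`), `boundaries` (tibble `bin`, `start`, `end`, `strength`),
#'   `resolution`, `chrom`.
#' @export
insulation_scores <- function(cm, square = 6e5, delta = 2e5,
                              threshold = 0.5,
                              method = c("strength", "insulation")) {
  method <- match.arg(method)
  res <- cm$resolution
  if (square %% res != 0 || delta %% res != 0) {
    abort("resolution must divide square and delta sizes")
  }
  w <- square %/% res
  d <- delta %/% res
  n <- cm$n_bins
  empty <- function() {
    structure(list(
      profile = tibble(bin = integer(), start = integer(), end = integer(),
                       insulation = double(), score = double(),
                       delta = double()),
      boundaries = tibble(bin = integer(), start = integer(),
                          end = integer(), strength = double()),
      resolution = res, chrom = cm$chrom), class = "insulation_profile")
  }
  if (n < 2 * w + 1) {
    warn("chromosome shorter than twice the insulation square")
    return(empty())
  }
  ins <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    ins[i] <- mean(cm$mat[(i - w):(i - 1), (i + 1):(i + w)])
  }
  valid <- !is.na(ins)
  nz_mean <- mean(ins[valid & ins > 0])
  score <- ifelse(valid & ins > 0, log2(ins / nz_mean), NA_real_)

  dl <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- (i - d):(i - 1); hi <- (i + 1):(i + d)
    lo <- lo[lo >= 1]; hi <- hi[hi <= n]
    l <- score[lo]; r <- score[hi]
    if (length(l) == 0 || length(r) == 0 ||
        all(is.na(l)) || all(is.na(r))) next
    dl[i] <- mean(l, na.rm = TRUE) - mean(r, na.rm = TRUE)
  }

  if (method == "strength") {
    bnd <- list()
    for (i in seq_len(n - 1)) {
      if (is.na(dl[i]) || is.na(dl[i + 1])) next
      if (dl[i] >= 0 && dl[i + 1] < 0) {
        # boundary at the lower-insulation bin of the crossing pair
        cand <- c(i, i + 1)
        b <- cand[which.min(score[cand])]
        lo <- max(1, i - d):i
        hi <- (i + 1):min(n, i + 1 + d)
        strength <- max(dl[lo], na.rm = TRUE) - min(dl[hi], na.rm = TRUE)
        if (is.finite(strength) && strength >= threshold) {
          bnd[[length(bnd) + 1]] <- tibble(bin = b - 1L, strength = strength)
        }
      }
    }
    boundaries <- if (length(bnd)) bind_rows(bnd) else
      tibble(bin = integer(), strength = double())
  } else {
    hit <- which(!is.na(score) & -score >= threshold)
    boundaries <- tibble(bin = hit - 1L, strength = -score[hit])
  }
  boundaries <- boundaries |>
    mutate(start = .data$bin * res, end = (.data$bin + 1L) * res) |>
    select("bin", "start", "end", "strength")

  profile <- tibble(bin = seq_len(n) - 1L,
                    start = (seq_len(n) - 1L) * res,
                    end = seq_len(n) * res,
                    insulation = ins, score = score, delta = dl)
  structure(list(profile = profile, boundaries = boundaries,
                 resolution = res, chrom = cm$chrom),
            class = "insulation_profile")
}

#' @export
print.insulation_profile <- function(x, ...) {
  cat(sprintf("<insulation_profile> %s: %d bins at %d bp, %d boundaries\n",
              x$chrom, nrow(x$profile), x$resolution, nrow(x$boundaries)))
  invisible(x)
}

# fraction of intervals overlapping (>= 1 bp) any boundary-bin interval
overlap_fraction <- function(intervals, bins) {
  if (nrow(intervals) == 0) return(NA_real_)
  if (nrow(bins) == 0) return(0)
  hits <- GenomicRanges::findOverlaps(as_granges0(intervals),
                                      as_granges0(bins), minoverlap = 1L)
  length(unique(S4Vectors::queryHits(hits))) / nrow(intervals)
}

#' Enrichment of SE constituents at TAD boundaries
#'
#' For each SE subtype, the fraction of constituent enhancers overlapping
#' a TAD-boundary bin is compared with the same fraction in `n_draws`
#' random samples of `n_sample` regular enhancers (unified peaks outside
#' any SE). Fold enrichment = SE fraction / sampled fraction, one value
#' per draw; draws with zero fraction yield `NA` folds (flagged, no
#' pseudocount).
#'
#' @param ses_by_type Named list of constituent-interval tibbles (`chrom`,
#'   `start`, `end`), one per SE subtype.
#' @param boundaries Boundary-bin tibble with `chrom`, `start`, `end`
#'   (e.g. `insulation_scores(...)$boundaries` plus the chromosome).
#' @param regular_enhancers Tibble of regular-enhancer intervals to sample
#'   from.
#' @param n_sample Enhancers per draw (default 1000).
#' @param n_draws Number of draws (default 20).
#' @param seed Integer seed making the draws reproducible.
#' @return Tibble `type`, `draw`, `se_fraction`, `sample_fraction`,
#'   `fold`.
#' @export
boundary_enrichment <- function(ses_by_type, boundaries, regular_enhancers,
                                n_sample = 1000, n_draws = 20, seed = 1) {
  if (!"chrom" %in% names(boundaries)) abort("boundaries need a chrom column")
  seeds <- derive_seeds(seed, n_draws)
  draw_frac <- map_dbl(seq_len(n_draws), function(k) {
    idx <- with_seed(seeds[k],
                     sample.int(nrow(regular_enhancers), n_sample,
                                replace = nrow(regular_enhancers) < n_sample))
    overlap_fraction(regular_enhancers[idx, , drop = FALSE], boundaries)
  })
  out <- imap(ses_by_type, function(cons, type) {
    sf <- overlap_fraction(cons, boundaries)
    tibble(type = type, draw = seq_len(n_draws), se_fraction = sf,
           sample_fraction = draw_frac,
           fold = ifelse(draw_frac > 0, sf / draw_frac, NA_real_))
  })
  bind_rows(out)
}

#' Per-stage FIRE scores and FIRE calls
#'
#' The raw FIRE score of a bin is the total cis contact count to bins 1 to
#' `local_range / resolution` bins away (short-range, self-diagonal
#' excluded). Scores are normalized within each stage as a z-score of
#' `log1p(raw)` over usable (non-empty) bins, then quantile-normalized
#' across stages. Within each stage the top `top_fraction` of usable bins
#' (ceiling; ties broken by bin index) are flagged as frequently
#' interacting regions (FIREs).
#'
#' @param cms Named list of `contact_matrix` objects, one per stage, on the
#'   same binning (typically 50 kb resolution).
#' @param local_range Maximum local distance in bp (default 2e5, i.e. 1-4
#'   bins at 50 kb).
#' @param top_fraction FIRE quantile (default 0.10).
#' @return Tibble `stage`, `bin` (0-based), `start`, `end`, `raw_score`,
#'   `norm_score`, `fire_flag`, restricted to usable bins.
#' @export
fire_scores <- function(cms, local_range = 2e5, top_fraction = 0.10) {
  res <- cms[[1]]$resolution
  n <- cms[[1]]$n_bins
  for (cm in cms) {
    if (cm$resolution != res || cm$n_bins != n) {
      abort("contact matrices must share binning")
    }
  }
  k <- local_range %/% res
  stages <- names(cms) %||% paste0("s", seq_along(cms))

  raw <- sapply(cms, function(cm) {
    sapply(seq_len(n), function(i) {
      j <- setdiff(max(1, i - k):min(n, i + k), i)
      sum(cm$mat[i, j])
    })
  })
  usable <- rowSums(sapply(cms, function(cm) rowSums(cm$mat))) > 0
  if (!any(usable)) abort("no usable bins")

  z <- apply(raw[usable, , drop = FALSE], 2, function(v) {
    lv <- log1p(v)
    if (sd(lv) == 0) return(lv * 0)
    (lv - mean(lv)) / sd(lv)
  })
  qn <- if (ncol(z) > 1) limma::normalizeQuantiles(z, ties = TRUE) else z

  n_use <- sum(usable)
  n_fire <- ceiling(top_fraction * n_use)
  bins <- which(usable) - 1L
  out <- map(seq_along(stages), function(s) {
    sc <- qn[, s]
    ord <- order(-sc, bins) # ties broken by bin index
    flag <- logical(n_use)
    flag[ord[seq_len(n_fire)]] <- TRUE
    tibble(stage = stages[s], bin = bins,
           start = bins * res, end = (bins + 1L) * res,
           raw_score = raw[usable, s], norm_score = sc, fire_flag = flag)
  })
  bind_rows(out)
}

#' Fold enrichment of SE regions over FIRE bins
#'
#' Compares the fraction of SE regions overlapping a FIRE bin against
#' length-matched random regions drawn uniformly on the same chromosome,
#' per subtype and draw.
#'
#' @param ses_by_type Named list of SE-region tibbles (`chrom`, `start`,
#'   `end`).
#' @param fires FIRE-bin tibble with `chrom`, `start`, `end` (e.g.
#'   filtered `fire_scores()` output for one stage plus the chromosome).
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param n_draws Number of random draws (default 20).
#' @param seed Integer seed.
#' @return Tibble `type`, `draw`, `se_fraction`, `random_fraction`,
#'   `fold`.
#' @export
fire_enrichment <- function(ses_by_type, fires, chrom_sizes, n_draws = 20,
                            seed = 1) {
  seeds <- derive_seeds(seed, n_draws)
  out <- imap(ses_by_type, function(regions, type) {
    sf <- overlap_fraction(regions, fires)
    rf <- map_dbl(seq_len(n_draws), function(k) {
      rand <- with_seed(seeds[k] + match(type, names(ses_by_type)), {
        len <- regions$end - regions$start
        maxs <- chrom_sizes[regions$chrom] - len
        st <- floor(stats::runif(nrow(regions), 0, pmax(1, maxs)))
        tibble(chrom = regions$chrom, start = st, end = st + len)
      })
      overlap_fraction(rand, fires)
    })
    tibble(type = type, draw = seq_len(n_draws), se_fraction = sf,
           random_fraction = rf,
           fold = ifelse(rf > 0, sf / rf, NA_real_))
  })
  bind_rows(out)
}

#' Compartment-category distribution of SE subtypes
#'
#' Assigns each SE to the compartment category of its midpoint bin and
#' tests independence of subtype and category with a chi-square test.
#'
#' @param ses_by_type Named list of SE-region tibbles (`chrom`, `start`,
#'   `end`).
#' @param track Compartment track from [categorize_compartments()].
#' @return A list: `table` (subtype x category contingency table),
#'   `p_value` (chi-square; `NA` with a warning when the table is
#'   degenerate), `counts` tibble.
#' @export
se_compartment_distribution <- function(ses_by_type, track) {
  rows <- imap(ses_by_type, function(regions, type) {
    if (nrow(regions) == 0) return(NULL)
    mid <- floor((regions$start + regions$end) / 2)
    cat_of <- map_chr(seq_len(nrow(regions)), function(i) {
      hit <- which(track$chrom == regions$chrom[i] &
                     track$start <= mid[i] & mid[i] < track$end)
      if (length(hit) == 0) "unassigned" else track$category[hit[1]]
    })
    tibble(type = type, category = cat_of)
  })
  counts <- bind_rows(rows) |>
    dplyr::count(.data$type, .data$category, name = "n")
  tab <- stats::xtabs(n ~ type + category, data = counts)
  p <- NA_real_
  if (nrow(tab) >= 2 && ncol(tab) >= 2) {
    # plain Pearson chi-square, no continuity correction
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  } else {
    warn("degenerate contingency table: chi-square not computed")
  }
  list(table = tab, p_value = p, counts = counts)
}
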