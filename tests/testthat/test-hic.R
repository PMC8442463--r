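uniform_cm <- function(n, value = 10, res = 40000L, chrom = "chrU") {
  structure(list(chrom = chrom, resolution = res, n_bins = n,
                 mat = matrix(value, n, n)), class = "contact_matrix")
}

two_block_cm <- function(n = 80, b = 40, res = 40000L) {
  block <- rep(1:2, c(b, n - b))
  m <- ifelse(outer(block, block, `==`), 40, 0.05)
  diag(m) <- 80
  structure(list(chrom = "chrB", resolution = res, n_bins = n, mat = m),
            class = "contact_matrix")
}

test_that("contact matrices are symmetrized from either triangle", {
  trip <- tibble::tibble(chrom = "chrZ", bin_i = c(0, 2, 1),
                         bin_j = c(1, 0, 1), count = c(5, 7, 3))
  cm1 <- contact_matrix(trip, resolution = 50000)
  trip_t <- tibble::tibble(chrom = "chrZ", bin_i = trip$bin_j,
                           bin_j = trip$bin_i, count = trip$count)
  cm2 <- contact_matrix(trip_t, resolution = 50000)
  expect_equal(cm1$mat, cm2$mat)
  expect_equal(cm1$mat, t(cm1$mat))
  expect_equal(cm1$mat[1, 2], 5)
  expect_equal(cm1$mat[3, 1], 7)
})

test_that("compartment categories follow the PC1 sign rule", {
  bins <- tibble::tibble(chrom = "chrC", start = (0:4) * 5e4,
                         end = (1:5) * 5e4)
  first <- dplyr::mutate(bins, pc1 = c(0.8, -0.2, -0.3, 0.4, 0.0))
  last <- dplyr::mutate(bins, pc1 = c(0.3, 0.5, -0.1, -0.6, 0.5))
  tr <- categorize_compartments(first, last)
  expect_equal(tr$category,
               c("stableA", "BtoA", "stableB", "AtoB", "unassigned"))
  bad <- dplyr::mutate(bins[1:4, ], pc1 = 1)
  expect_error(categorize_compartments(first, bad), "binning")
})

test_that("uniform matrices give flat insulation and no boundaries", {
  prof <- insulation_scores(uniform_cm(80))
  expect_equal(nrow(prof$boundaries), 0)
  sc <- prof$profile$score
  expect_true(all(abs(sc[!is.na(sc)]) < 1e-10))
})

test_that("a planted two-block structure yields one boundary within 1 bin", {
  prof <- insulation_scores(two_block_cm(n = 80, b = 40))
  expect_equal(nrow(prof$boundaries), 1)
  expect_lte(abs(prof$boundaries$bin - 39), 1) # 0-based boundary bin
  expect_gte(prof$boundaries$strength, 0.5)
})

test_that("insulation normalization centers log-ratios near zero", {
  set.seed(8)
  cm <- uniform_cm(100)
  cm$mat <- cm$mat * matrix(rlnorm(100 * 100, 0, 0.2), 100, 100)
  cm$mat <- (cm$mat + t(cm$mat)) / 2
  prof <- insulation_scores(cm)
  expect_lt(abs(mean(prof$profile$score, na.rm = TRUE)), 0.1)
})

test_that("short chromosomes give an empty profile with a warning", {
  expect_warning(prof <- insulation_scores(uniform_cm(20)), "shorter")
  expect_equal(nrow(prof$profile), 0)
  expect_equal(nrow(prof$boundaries), 0)
})

test_that("insulation output is invariant to symmetric storage order", {
  cm <- two_block_cm()
  cm_upper <- cm
  cm_upper$mat[lower.tri(cm_upper$mat)] <-
    t(cm_upper$mat)[lower.tri(cm_upper$mat)]
  expect_equal(insulation_scores(cm)$profile,
               insulation_scores(cm_upper)$profile)
})

test_that("raw FIRE score is the hand sum of short-range neighbors", {
  # 6x6 printed fixture at 50 kb; local range 200 kb = 4 bins
  m <- matrix(0, 6, 6)
  m[1, 2] <- 3; m[2, 3] <- 5; m[2, 4] <- 7; m[2, 5] <- 11; m[2, 6] <- 13
  m <- m + t(m)
  diag(m) <- 99 # self-diagonal must be excluded
  cm <- structure(list(chrom = "chrF", resolution = 50000L, n_bins = 6L,
                       mat = m), class = "contact_matrix")
  fs <- fire_scores(list(s0 = cm))
  # bin 2 (1-based) neighbors within 4 bins: bins 1,3,4,5,6
  expect_equal(fs$raw_score[fs$bin == 1], 3 + 5 + 7 + 11 + 13)
  expect_equal(fs$raw_score[fs$bin == 0], 3)
})

test_that("uniform FIRE scores break ties by bin index at exact top-decile size", {
  cm <- uniform_cm(50, value = 4, res = 50000L, chrom = "chrF")
  fs <- fire_scores(list(s0 = cm, s1 = cm))
  for (s in c("s0", "s1")) {
    d <- fs[fs$stage == s, ]
    expect_equal(sum(d$fire_flag), ceiling(0.1 * 50))
    # interior raw scores all equal (edge bins have fewer neighbors);
    # ties resolved toward low bin indices, starting at the first
    # interior bin (0-based bin 4 at a 4-bin local range)
    expect_equal(length(unique(d$raw_score[d$bin %in% 4:45])), 1)
    expect_equal(d$bin[d$fire_flag], 4:8)
  }
})

test_that("an inflated-local-contact bin is a FIRE in every stage", {
  set.seed(10)
  n <- 120
  base <- 60 / pmax(abs(outer(1:n, 1:n, `-`)), 1)
  diag(base) <- 100
  mk <- function() {
    m <- matrix(rpois(n * n, base), n, n)
    m <- pmax(m, t(m))
    lo <- 56:64
    m[60, lo] <- m[60, lo] * 10
    m[lo, 60] <- m[60, lo]
    structure(list(chrom = "chrF", resolution = 50000L, n_bins = n,
                   mat = m), class = "contact_matrix")
  }
  fs <- fire_scores(list(s0 = mk(), s1 = mk(), s2 = mk()))
  for (s in unique(fs$stage)) {
    d <- fs[fs$stage == s, ]
    expect_true(d$fire_flag[d$bin == 59]) # 0-based bin 59 = planted bin 60
    expect_equal(sum(d$fire_flag), ceiling(0.1 * n))
  }
})

test_that("boundary enrichment is seeded, arithmetic, and null-calibrated", {
  set.seed(12)
  pool <- tibble::tibble(chrom = "chrB",
                         start = sort(sample.int(4e6, 400)) * 10)
  pool$end <- pool$start + 1000
  bnd_bins <- tibble::tibble(chrom = "chrB",
                             start = seq(0, 4e7, by = 4e5),
                             end = seq(0, 4e7, by = 4e5) + 4e4)
  # SE constituents drawn from the same pool: mean fold ~ 1
  cons <- pool[sample.int(400, 120), ]
  out <- boundary_enrichment(list(null = cons), bnd_bins, pool,
                             n_sample = 200, n_draws = 20, seed = 9)
  expect_equal(nrow(out), 20)
  expect_gt(mean(out$fold, na.rm = TRUE), 0.5)
  expect_lt(mean(out$fold, na.rm = TRUE), 1.8)
  # determinism
  out2 <- boundary_enrichment(list(null = cons), bnd_bins, pool,
                              n_sample = 200, n_draws = 20, seed = 9)
  expect_identical(out, out2)
  # pure arithmetic when fractions are forced
  expect_equal(unique(out$fold), unique(out$se_fraction /
                                          out$sample_fraction))
})

test_that("FIRE enrichment is reproducible and null-calibrated", {
  set.seed(13)
  fires <- tibble::tibble(chrom = "chrF", start = seq(0, 95, by = 10) * 5e4,
                          end = (seq(0, 95, by = 10) + 1) * 5e4)
  regions <- tibble::tibble(chrom = "chrF",
                            start = sample.int(90, 40) * 5e4)
  regions$end <- regions$start + 2e4
  sizes <- c(chrF = 5e6)
  e1 <- fire_enrichment(list(all = regions), fires, sizes, seed = 4)
  e2 <- fire_enrichment(list(all = regions), fires, sizes, seed = 4)
  expect_identical(e1, e2)
  expect_gt(mean(e1$fold, na.rm = TRUE), 0.4)
  expect_lt(mean(e1$fold, na.rm = TRUE), 2.5)
})

test_that("compartment distribution tables match hand counts and chi-square", {
  track <- tibble::tibble(chrom = "chrC", start = (0:3) * 5e4,
                          end = (1:4) * 5e4,
                          category = c("stableA", "stableA", "stableB",
                                       "BtoA"))
  mk_regions <- function(bins) {
    tibble::tibble(chrom = "chrC", start = bins * 5e4 + 1e4,
                   end = bins * 5e4 + 2e4)
  }
  out <- se_compartment_distribution(
    list(Con = mk_regions(c(0, 1, 2, 2)), DN = mk_regions(c(2, 2, 3, 3))),
    track)
  tab <- out$table
  expect_equal(unname(tab["Con", "stableA"]), 2)
  expect_equal(unname(tab["Con", "stableB"]), 2)
  expect_equal(unname(tab["DN", "stableB"]), 2)
  expect_equal(unname(tab["DN", "BtoA"]), 2)
  # textbook Pearson chi-square on the observed table
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - exp_tab)^2 / exp_tab)
  expect_equal(out$p_value,
               stats::pchisq(x2, df = (nrow(tab) - 1) * (ncol(tab) - 1),
                             lower.tail = FALSE))
  # degenerate: single category
  expect_warning(
    deg <- se_compartment_distribution(list(Con = mk_regions(c(0, 1))),
                                       track[1:2, ]),
    "degenerate")
  expect_true(is.na(deg$p_value))
})
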