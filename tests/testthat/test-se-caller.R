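test_that("stitching chains peaks within the stitch distance", {
  pk <- tibble::tibble(chrom = "chr1", start = c(0, 10000),
                       end = c(1000, 11000), peak_id = c("a", "b"))
  one <- stitch_peaks(pk, 12500) # gap 9000 <= 12500
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 0)
  expect_equal(one$end, 11000)
  expect_setequal(one$constituents[[1]], c("a", "b"))

  far <- tibble::tibble(chrom = "chr1", start = c(0, 14000),
                        end = c(1000, 15000), peak_id = c("a", "b"))
  expect_equal(nrow(stitch_peaks(far, 12500)), 2) # gap 13000 > 12500

  # transitive chaining: consecutive gaps small, total span large
  chain <- tibble::tibble(chrom = "chr1",
                          start = c(0, 10000, 20000),
                          end = c(1000, 11000, 21000),
                          peak_id = c("a", "b", "c"))
  st <- stitch_peaks(chain, 12500)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_constituents, 3)
})

test_that("stitching partitions the input peaks", {
  set.seed(3)
  pk <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 120, replace = TRUE),
                       start = sample.int(4e5, 120))
  pk$end <- pk$start + 1500
  pk$peak_id <- paste0("p", seq_len(nrow(pk)))
  st <- stitch_peaks(pk, 12500)
  members <- unlist(st$constituents)
  expect_setequal(members, pk$peak_id)
  expect_equal(length(members), nrow(pk)) # each peak in exactly one region
  expect_equal(nrow(stitch_peaks(pk[0, ], 12500)), 0)
})

test_that("rank-curve elbow calls only the outlier in a hand instance", {
  reg <- tibble::tibble(region_id = paste0("r", 1:4),
                        signal = c(1, 2, 3, 100))
  rk <- se_rank_threshold(reg)
  expect_equal(rk$superenhancers$region_id, "r4")
  expect_equal(rk$cutoff_signal, 3)
  expect_equal(rk$cutoff_signal, oracle_elbow_cutoff(reg$signal))
})

test_that("identical signals yield zero super-enhancers with a warning", {
  reg <- tibble::tibble(region_id = paste0("r", 1:5), signal = rep(2, 5))
  expect_warning(rk <- se_rank_threshold(reg), "identical")
  expect_equal(nrow(rk$superenhancers), 0)
})

test_that("elbow cutoff matches the brute-force tangent oracle on random instances", {
  set.seed(77)
  for (k in 1:100) {
    n <- sample(5:200, 1)
    s <- switch(1 + k %% 3,
                rexp(n, 1 / 10),
                rlnorm(n, 2, 1),
                c(runif(n - 3, 0, 5), runif(3, 50, 100))) # heavy tail
    s <- s + seq_len(n) * 1e-9 # break exact ties deterministically
    rk <- se_rank_threshold(tibble::tibble(region_id = paste0("r", 1:n),
                                           signal = s))
    expect_equal(rk$cutoff_signal, oracle_elbow_cutoff(s))
  }
})

test_that("adding a dominant region never drops still-above-cutoff calls", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(10:80, 1)
    s <- rlnorm(n, 1, 1)
    base <- se_rank_threshold(tibble::tibble(region_id = paste0("r", 1:n),
                                             signal = s))
    s2 <- c(s, max(s) * 50)
    ext <- se_rank_threshold(tibble::tibble(region_id = paste0("r", 1:(n + 1)),
                                            signal = s2))
    kept <- base$superenhancers$region_id[
      base$superenhancers$signal > ext$cutoff_signal]
    expect_true(all(kept %in% ext$superenhancers$region_id))
  }
})

test_that("promoter containment distinguishes overlap from full containment", {
  tss <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 10000,
                        strand = "+")
  cons <- tibble::tibble(chrom = "chr1",
                         start = c(9000, 7500, 50000),
                         end = c(11000, 10500, 51000),
                         peak_id = c("inside", "straddle", "far"))
  flags <- is_promoter_peak(cons, tss, tss_window = 2000)
  expect_equal(flags, c(TRUE, FALSE, FALSE))
})

test_that("the >= 50% promoter rule keeps 1-of-4 and removes 1-of-2", {
  # two stitched candidates, both far above a cluster of background regions
  mk_peaks <- function(slot, k) {
    st <- slot + (seq_len(k) - 1) * 3000
    tibble::tibble(chrom = "chr1", start = st, end = st + 1000,
                   stage = "s0")
  }
  pk <- dplyr::bind_rows(
    mk_peaks(0, 4), mk_peaks(1e6, 2),
    tibble::tibble(chrom = "chr1", start = seq(2e6, 2e6 + 40 * 5e4, 5e4),
                   end = seq(2e6, 2e6 + 40 * 5e4, 5e4) + 1000, stage = "s0"))
  up <- unify_peaks(pk)
  ids <- up$peaks$peak_id
  counts <- tibble::tibble(peak_id = ids, stage = "s0",
                           count = ifelse(up$peaks$start < 2e6, 5000, 50))
  sm <- rpm_matrix(up, counts, tibble::tibble(stage = "s0",
                                              total_reads = 1e6))
  # one promoter TSS inside the 4-peak SE, one inside the 2-peak SE
  tss <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                        tss = c(500, 1e6 + 500), strand = "+")
  call <- suppressWarnings(
    call_superenhancers(up, sm, tss = tss, calling_stage = "s0"))
  expect_equal(nrow(call$ses), 1)
  expect_equal(call$ses$n_constituents, 4)
  expect_equal(call$ses$promoter_fraction, 0.25) # retained below 0.5
  expect_equal(nrow(call$removed_promoter_heavy), 1)
  expect_equal(call$removed_promoter_heavy$promoter_fraction, 0.5)
})

test_that("SE calls are invariant to input peak order", {
  b <- small_bundle()
  up1 <- unify_peaks(b$peaks, stage_levels = b$stages)
  shuffled <- b$peaks[sample.int(nrow(b$peaks)), ]
  up2 <- unify_peaks(shuffled, stage_levels = b$stages)
  cts1 <- sedyn:::map_counts_to_unified(b$counts, up1)
  cts2 <- sedyn:::map_counts_to_unified(b$counts, up2)
  sm1 <- quantile_normalize(rpm_matrix(up1, cts1, b$library_sizes))
  sm2 <- quantile_normalize(rpm_matrix(up2, cts2, b$library_sizes))
  c1 <- call_superenhancers(up1, sm1, tss = b$tss)
  c2 <- call_superenhancers(up2, sm2, tss = b$tss)
  expect_equal(c1$ses[, c("chrom", "start", "end", "signal")],
               c2$ses[, c("chrom", "start", "end", "signal")])
})
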