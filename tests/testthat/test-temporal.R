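test_that("rsd follows the sd/mean definition with the zero convention", {
  expect_equal(rsd(c(5, 5, 5)), 0)
  expect_equal(rsd(c(1, 3)), 0.5) # population sd 1 over mean 2
  expect_equal(rsd(c(0, 0, 0)), 0)
  expect_error(rsd(c(1, -1)), "nonnegative")
})

test_that("SE vectors reproduce constituents exactly when n equals 4", {
  # rows constructed with distinct RSDs; rownames deliberately scrambled
  sub <- rbind(
    d = c(0, 0, 10, 10, 10), # highest RSD
    a = c(5, 5, 5, 5, 5),    # zero RSD
    c = c(2, 4, 6, 8, 10),
    b = c(4, 5, 5, 5, 6)
  )
  colnames(sub) <- paste0("t", 0:4)
  v <- build_se_vector(sub, normalize = FALSE)
  ord <- order(apply(sub, 1, rsd), rownames(sub))
  expected <- as.vector(t(sub[ord, ]))
  expect_equal(unname(v), expected)
})

test_that("degenerate and interpolation cases follow the stated rules", {
  one <- matrix(c(1, 2, 3), nrow = 1,
                dimnames = list("only", paste0("t", 0:2)))
  v1 <- build_se_vector(one, normalize = FALSE)
  expect_equal(unname(v1), rep(c(1, 2, 3), 4))

  # n = 7 with per-stage sorted profile 0..6: representatives at fractional
  # indices 0, 2, 4, 6
  sub <- matrix(rep(0:6, 3), nrow = 7,
                dimnames = list(paste0("e", 1:7), paste0("t", 0:2)))
  # give rows increasing RSD-free ordering: identical rows across stages, so
  # RSD ties resolve by id and the sorted axis is e1..e7 with values 0..6
  v <- build_se_vector(sub, normalize = FALSE)
  expect_equal(unname(v), rep(c(0, 2, 4, 6), each = 3))
})

test_that("SE vectors are scale-equivariant and max-normalized on request", {
  set.seed(9)
  sub <- matrix(rexp(6 * 5), 6, 5,
                dimnames = list(paste0("e", 1:6), paste0("t", 0:4)))
  v <- build_se_vector(sub, normalize = FALSE)
  v3 <- build_se_vector(sub * 3, normalize = FALSE)
  expect_equal(v3, v * 3)
  vn <- build_se_vector(sub, normalize = TRUE)
  expect_equal(max(vn), 1)
  expect_equal(unname(vn), unname(v / max(v)))
})

test_that("representatives preserve per-stage order on monotone profiles", {
  # constituents whose per-stage values increase along the RSD-sorted axis
  sub <- rbind(a = c(1, 1, 1), b = c(2, 2.5, 2), c = c(4, 6, 5),
               d = c(8, 14, 10), e = c(16, 30, 20))
  colnames(sub) <- paste0("t", 0:2)
  v <- build_se_vector(sub, normalize = FALSE)
  reps <- matrix(v, nrow = 4, byrow = TRUE)
  for (s in 1:3) expect_true(all(diff(reps[, s]) >= 0))
})

test_that("consensus k-means recovers well-separated blobs exactly", {
  set.seed(1)
  centers <- rbind(rep(0, 8), rep(10, 8), c(rep(0, 4), rep(10, 4)))
  truth <- rep(1:3, each = 20)
  vm <- centers[truth, ] + matrix(rnorm(60 * 8, 0, 0.3), 60, 8)
  rownames(vm) <- paste0("se", 1:60)
  cons <- consensus_kmeans(vm, K = 3, n_rounds = 25, master_seed = 5)
  expect_equal(ari(cons$assignment$cluster, truth), 1)
})

test_that("consensus assignment is deterministic and order-invariant", {
  set.seed(2)
  vm <- rbind(matrix(rnorm(40, 0, 0.5), 10, 4),
              matrix(rnorm(40, 6, 0.5), 10, 4),
              matrix(rnorm(40, 12, 0.5), 10, 4))
  rownames(vm) <- paste0("se", 1:30)
  c1 <- consensus_kmeans(vm, K = 3, n_rounds = 20, master_seed = 7)
  c2 <- consensus_kmeans(vm, K = 3, n_rounds = 20, master_seed = 7)
  expect_identical(c1$assignment, c2$assignment)
  expect_identical(c1$coassociation, c2$coassociation)

  perm <- sample.int(30)
  c3 <- consensus_kmeans(vm[perm, ], K = 3, n_rounds = 20, master_seed = 7)
  back <- c3$assignment[match(c1$assignment$se_id, c3$assignment$se_id), ]
  expect_equal(ari(back$cluster, c1$assignment$cluster), 1)

  expect_error(consensus_kmeans(vm[1:2, ], K = 3), "fewer vectors")
})

test_that("cluster labeling maps archetype trajectories to Con/TH/DN", {
  t_n <- 5
  flat <- rep(1, t_n)
  ramp <- seq(0.1, 1, length.out = t_n)
  late <- c(0, 0, 0, 0.1, 1)
  mk <- function(profile, n, jit) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      rep(pmax(profile + rnorm(t_n, 0, jit), 0), 4)
    }))
  }
  set.seed(4)
  vm <- rbind(mk(flat, 12, 0.02), mk(ramp, 12, 0.02), mk(late, 12, 0.02))
  rownames(vm) <- paste0("se", 1:36)
  cons <- consensus_kmeans(vm, K = 3, n_rounds = 20, master_seed = 3)
  lab <- label_clusters(cons, vm, n_stages = t_n)
  got <- lab$cluster_to_label[as.character(cons$assignment$cluster)]
  expect_equal(unname(got[1:12]), rep("Con", 12))
  expect_equal(unname(got[13:24]), rep("TH", 12))
  expect_equal(unname(got[25:36]), rep("DN", 12))
  # AUC ordering Con > TH > DN
  auc <- lab$labels$auc[match(c("Con", "TH", "DN"), lab$labels$label)]
  expect_true(all(diff(auc) < 0))
})

test_that("labeling guards degenerate clusters and non-3 K", {
  vm <- rbind(matrix(rep(c(1, 1, 1), 4), 6, 12, byrow = TRUE))
  rownames(vm) <- paste0("se", 1:6)
  cons <- list(assignment = tibble::tibble(se_id = rownames(vm),
                                           cluster = rep(1:3, 2)),
               K = 3)
  expect_error(label_clusters(cons, vm, n_stages = 3), "indistinguishable")

  set.seed(6)
  vm2 <- rbind(matrix(rnorm(24, 0, .1), 4, 6),
               matrix(rnorm(24, 5, .1), 4, 6),
               matrix(rnorm(24, 10, .1), 4, 6),
               matrix(rnorm(24, 15, .1), 4, 6))
  vm2 <- pmax(vm2, 0)
  rownames(vm2) <- paste0("se", 1:16)
  cons4 <- consensus_kmeans(vm2, K = 4, n_rounds = 10, master_seed = 2)
  lab4 <- label_clusters(cons4, vm2, n_stages = 3)
  expect_true(all(grepl("^cluster_", lab4$labels$label)))
  expect_false(any(c("Con", "TH", "DN") %in% lab4$labels$label))
})

test_that("element commission timing follows the alpha-of-max rule", {
  sub <- rbind(
    always = c(5, 5, 5, 5, 5),
    late = c(0, 0, 0, 5, 5),
    mid = c(0, 3, 5, 5, 5),
    dead = c(0, 0, 0, 0, 0)
  )
  colnames(sub) <- paste0("t", 0:4)
  tm <- classify_element_timing(sub, alpha = 0.5)
  expect_equal(tm$commission_stage, c(0L, 3L, 1L, NA))
  expect_equal(tm$timing_class, c("early", "late", "intermediate",
                                  "undefined"))
  expect_error(classify_element_timing(sub, alpha = 0), "alpha")
})

test_that("timing table restricts to TH SEs and covers their constituents", {
  b <- small_bundle()
  res <- run_se_pipeline(b, master_seed = 2)
  cl <- res$classification$classification
  th_ids <- cl$se_id[cl$label == "TH"]
  expect_setequal(unique(res$timing$se_id), th_ids)
  n_cons <- sum(res$se_call$ses$n_constituents[
    res$se_call$ses$se_id %in% th_ids])
  expect_equal(nrow(res$timing), n_cons)
  expect_true(all(res$timing$timing_class %in%
                    c("early", "intermediate", "late", "undefined")))
})
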