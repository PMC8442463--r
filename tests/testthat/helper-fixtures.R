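# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Full-size bundle at the study conditions (300 SEs, T = 5, noise 0.1).
default_bundle <- function() {
  cached("default_bundle", simulate_se_bundle(master_seed = 1))
}

default_pipeline <- function() {
  cached("default_pipeline", run_se_pipeline(default_bundle(), master_seed = 1))
}

# Small, fast bundle for unit-level tests.
small_bundle <- function() {
  cached("small_bundle",
         simulate_se_bundle(n_se_per_class = 20, hic = FALSE,
                            master_seed = 42))
}

# Match called SEs to planted SE loci by containment of coordinates.
match_truth <- function(ses, truth) {
  sapply(seq_len(nrow(ses)), function(i) {
    hit <- which(truth$chrom == ses$chrom[i] &
                   truth$start <= ses$start[i] & truth$end >= ses$end[i])
    if (length(hit) == 0) NA_integer_ else hit[1]
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Tiny two-stage peak table used across interval tests.
toy_stage_peaks <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100, 150, 500, 100),
    end = c(200, 250, 600, 300),
    stage = c("s0", "s1", "s1", "s0")
  )
}

# Independent brute-force oracle for the SE rank-curve elbow: scan every
# candidate point and check, pair by pair, that the slope-1 line through it
# lies at or below every curve point (support from below); the cutoff is the
# lowest-rank supporting point.
oracle_elbow_cutoff <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  support <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in seq_len(n)) {
      if (y[j] < y[i] + (x[j] - x[i]) - 1e-12) {
        ok <- FALSE
        break
      }
    }
    support[i] <- ok
  }
  s[which(support)[1]]
}
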