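#' @importFrom rlang %||% .data abort warn
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join distinct bind_rows rename n row_number across
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap
#' @importFrom stats kmeans hclust cutree as.dist sd cor approx wilcox.test
#'   chisq.test setNames quantile
#' @importFrom utils head tail
NULL

# Validate a peak/interval tibble (0-based half-open BED convention).
# Returns the tibble invisibly; aborts with the offending record otherwise.
check_intervals <- function(x, what = "interval") {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(x$start < x$end) | is.na(x$chrom) | x$chrom == "" |
                 is.na(x$start) | is.na(x$end) | x$start < 0)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf("malformed %s at row %d: %s:[%s,%s)",
                  what, i, x$chrom[i], format(x$start[i]), format(x$end[i])))
  }
  invisible(x)
}

# Convert a 0-based half-open interval tibble to GRanges (1-based closed).
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# Back to a 0-based half-open tibble.
granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Deterministic stream of sub-seeds derived from one master seed. Keeps every
# derived seed in [1, 2^31 - 2] so set.seed() is always valid.
derive_seeds <- function(master_seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run code under a temporary seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Star coding used throughout the figure-style group comparisons.
p_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}
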