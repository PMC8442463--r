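#' Merge per-stage peak sets into a unified peak set
#'
#' Pools H3K27ac peaks from all differentiation stages and merges any
#' overlapping or bookended intervals (the `bedtools merge -d 0` convention)
#' into a unified, non-overlapping peak set with stable ids. Each stage's
#' peaks are then re-expressed in unified coordinates: a unified peak is a
#' member of a stage when at least one of that stage's peaks overlaps it by
#' >= 1 bp.
#'
#' All coordinates follow the BED convention: 0-based, half-open
#' `[start, end)`. Bookended intervals (`end == start` of the next) merge;
#' bookended intervals share zero bases and therefore never count as
#' overlapping for membership.
#'
#' @param peaks A data frame of stage peaks with columns `chrom`, `start`,
#'   `end`, `stage` (stage label; ordered by `stage_levels`) and optionally
#'   `peak_id`.
#' @param stage_levels Character vector giving the temporal order of stages.
#'   Defaults to the order of first appearance in `peaks`.
#' @return A list with class `"unified_peaks"`:
#'   \describe{
#'     \item{peaks}{tibble `chrom`, `start`, `end`, `peak_id` — the merged,
#'       pairwise-disjoint unified peaks.}
#'     \item{membership}{tibble `peak_id`, `stage`, `stage_index` (0-based)
#'       with one row per (unified peak, contributing stage) pair.}
#'     \item{stages}{the ordered stage labels.}
#'   }
#' @examples
#' pk <- tibble::tibble(
#'   chrom = "chr1", start = c(100, 150, 500), end = c(200, 250, 600),
#'   stage = c("s0", "s1", "s1")
#' )
#' up <- unify_peaks(pk)
#' up$peaks
#' @export
unify_peaks <- function(peaks, stage_levels = NULL) {
  if (is.null(peaks) || nrow(peaks) == 0) abort("no stages")
  if (!"stage" %in% names(peaks)) abort("peaks need a `stage` column")
  check_intervals(peaks, "stage peak")
  stage_levels <- stage_levels %||% unique(as.character(peaks$stage))
  unknown <- setdiff(unique(as.character(peaks$stage)), stage_levels)
  if (length(unknown) > 0) {
    abort(paste0("stages not in stage_levels: ", paste(unknown, collapse = ", ")))
  }

  gr <- as_granges0(peaks)
  merged <- GenomicRanges::reduce(gr) # merges overlapping and bookended
  merged <- GenomicRanges::sort(merged)
  uni <- granges_to_tbl(merged)
  uni$peak_id <- sprintf("up%05d", seq_len(nrow(uni)))

  hits <- GenomicRanges::findOverlaps(gr, merged, minoverlap = 1L)
  membership <- tibble(
    peak_id = uni$peak_id[S4Vectors::subjectHits(hits)],
    stage = as.character(peaks$stage)[S4Vectors::queryHits(hits)]
  ) |>
    distinct() |>
    mutate(stage_index = match(.data$stage, stage_levels) - 1L) |>
    arrange(.data$peak_id, .data$stage_index)

  structure(
    list(peaks = uni, membership = membership, stages = stage_levels),
    class = "unified_peaks"
  )
}

#' @export
print.unified_peaks <- function(x, ...) {
  cat(sprintf("<unified_peaks> %d unified peaks across %d stages (%s)\n",
              nrow(x$peaks), length(x$stages),
              paste(x$stages, collapse = ", ")))
  print(x$peaks, n = 5)
  invisible(x)
}

#' Remove peaks overlapping a blacklist
#'
#' Drops every peak that overlaps (>= 1 bp) any blacklist interval, the
#' `bedtools intersect -v` behavior used to purge artifact-prone regions.
#' Bookended intervals share no bases and are retained.
#'
#' @param peaks Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param blacklist Data frame with the same interval columns; may be empty.
#' @return The `peaks` rows with zero blacklist overlap, as a tibble.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  check_intervals(peaks, "peak")
  if (is.null(blacklist) || nrow(blacklist) == 0) return(as_tibble(peaks))
  check_intervals(blacklist, "blacklist interval")
  hits <- GenomicRanges::findOverlaps(as_granges0(peaks),
                                      as_granges0(blacklist),
                                      minoverlap = 1L)
  drop <- unique(S4Vectors::queryHits(hits))
  as_tibble(peaks[setdiff(seq_len(nrow(peaks)), drop), , drop = FALSE])
}

#' Build the peak-by-stage RPM signal matrix
#'
#' Converts per-peak, per-stage read counts into reads per million mapped
#' reads: `RPM[p, s] = count[p, s] / (library_size[s] / 1e6)`. Peaks or
#' stages absent from `counts` get 0. No peak-length normalization is
#' applied; RPM is a pure library-size scaling.
#'
#' @param unified A `unified_peaks` object (or a data frame with `peak_id`).
#' @param counts Long data frame `peak_id`, `stage`, `count` (counts >= 0).
#' @param library_sizes Data frame `stage`, `total_reads` (> 0), one row per
#'   stage of the time course.
#' @return A `signal_matrix`: tibble with `peak_id` plus one numeric column
#'   per stage, attribute `normalized = FALSE` and `stages` in temporal
#'   order.
#' @export
rpm_matrix <- function(unified, counts, library_sizes) {
  peak_ids <- if (inherits(unified, "unified_peaks")) unified$peaks$peak_id else unified$peak_id
  stages <- if (inherits(unified, "unified_peaks")) unified$stages else unique(as.character(library_sizes$stage))
  if (any(library_sizes$total_reads <= 0)) abort("library size must be > 0")
  if (any(counts$count < 0)) abort("counts must be >= 0")
  missing_stage <- setdiff(stages, as.character(library_sizes$stage))
  if (length(missing_stage) > 0) {
    abort(paste0("no library size for stage(s): ",
                 paste(missing_stage, collapse = ", ")))
  }

  grid <- tidyr::expand_grid(peak_id = peak_ids, stage = stages)
  vals <- grid |>
    left_join(counts |> mutate(stage = as.character(.data$stage)),
              by = c("peak_id", "stage")) |>
    mutate(count = dplyr::coalesce(.data$count, 0)) |>
    left_join(library_sizes |> mutate(stage = as.character(.data$stage)),
              by = "stage") |>
    mutate(rpm = .data$count / (.data$total_reads / 1e6)) |>
    select("peak_id", "stage", "rpm") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "rpm")
  vals <- vals[match(peak_ids, vals$peak_id), c("peak_id", stages)]
  new_signal_matrix(vals, stages, normalized = FALSE)
}

new_signal_matrix <- function(tbl, stages, normalized) {
  structure(as_tibble(tbl),
            stages = stages, normalized = normalized,
            class = c("signal_matrix", class(as_tibble(tbl))))
}

#' Extract the numeric matrix from a signal matrix tibble
#'
#' @param x A `signal_matrix` (tibble with `peak_id` plus stage columns).
#' @return A numeric matrix, rownames = peak ids, colnames = stages.
#' @export
signal_values <- function(x) {
  stages <- attr(x, "stages") %||% setdiff(names(x), "peak_id")
  m <- as.matrix(x[, stages, drop = FALSE])
  rownames(m) <- x$peak_id
  m
}

#' Quantile-normalize the signal matrix across stages
#'
#' Makes the per-stage RPM distributions identical: the value at rank r in
#' any stage becomes the mean over stages of their rank-r values, with ties
#' averaged over the tied rank span. Mitigates stage-to-stage differences in
#' ChIP signal-to-noise. The heavy lifting is delegated to
#' `limma::normalizeQuantiles(ties = TRUE)`, which implements exactly this
#' rule.
#'
#' @param x A `signal_matrix` with `normalized = FALSE`.
#' @return A `signal_matrix` with identical column distributions and
#'   `normalized = TRUE`.
#' @export
quantile_normalize <- function(x) {
  if (isTRUE(attr(x, "normalized"))) abort("signal matrix already normalized")
  stages <- attr(x, "stages") %||% setdiff(names(x), "peak_id")
  m <- signal_values(x)
  if (ncol(m) < 2) {
    warn("single stage: quantile normalization is the identity")
    qn <- m
  } else {
    qn <- limma::normalizeQuantiles(m, ties = TRUE)
  }
  out <- as_tibble(as.data.frame(qn))
  names(out) <- stages
  out <- dplyr::bind_cols(tibble(peak_id = x$peak_id), out)
  new_signal_matrix(out, stages, normalized = TRUE)
}
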