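#' Stitch peaks into candidate super-enhancer regions
#'
#' Chains peaks on the same chromosome whose gap is at most
#' `stitch_distance` bp (transitively) into one stitched region, the ROSE
#' convention with the default 12.5 kb stitching distance. Every input peak
#' belongs to exactly one region.
#'
#' @param peaks Data frame with `chrom`, `start`, `end`, `peak_id`
#'   (0-based half-open).
#' @param stitch_distance Maximum gap in bp for two peaks to be stitched
#'   (default 12500).
#' @return A tibble of regions: `region_id`, `chrom`, `start`, `end`,
#'   `n_constituents`, `constituents` (list column of peak ids).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500) {
  if (stitch_distance <= 0) abort("stitch_distance must be > 0")
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  n_constituents = integer(), constituents = list()))
  }
  check_intervals(peaks, "peak")
  gr <- as_granges0(peaks)
  # reduce() merges when the gap is < min.gapwidth, so gap <= d needs d + 1
  regions <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1L)
  regions <- GenomicRanges::sort(regions)
  # every peak lies within exactly one stitched region
  hits <- GenomicRanges::findOverlaps(gr, regions, minoverlap = 1L)
  assign_region <- S4Vectors::subjectHits(hits)[match(seq_len(nrow(peaks)),
                                                      S4Vectors::queryHits(hits))]
  out <- granges_to_tbl(regions)
  out$region_id <- sprintf("sr%04d", seq_len(nrow(out)))
  out$constituents <- unname(split(peaks$peak_id, factor(assign_region, levels = seq_len(nrow(out)))))
  out$n_constituents <- lengths(out$constituents)
  out[, c("region_id", "chrom", "start", "end", "n_constituents", "constituents")]
}

#' Rank stitched regions by signal and locate the super-enhancer elbow
#'
#' ROSE-style geometric cutoff: regions are sorted ascending by total
#' H3K27ac signal, rank and signal are each min-max scaled to \[0, 1\], and
#' the cutoff is the point of the rank curve farthest below the unit-slope
#' diagonal — equivalently, the point where a line of slope 1 supports the
#' scaled curve from below (the slope-1 tangent of the hockey-stick plot).
#' Regions with signal strictly above the cutoff signal are called
#' super-enhancers; ties at the cutoff are excluded.
#'
#' @param regions Tibble of stitched regions with a numeric `signal` column
#'   (total constituent RPM at the calling stage).
#' @return A list of class `"se_rank"`: `superenhancers` (rows of `regions`
#'   above the cutoff, ranked descending by signal), `cutoff_signal`, and
#'   `curve` (tibble `rank`, `signal`, `scaled_rank`, `scaled_signal`,
#'   `is_se`).
#' @export
se_rank_threshold <- function(regions) {
  if (!"signal" %in% names(regions)) abort("regions need a `signal` column")
  n <- nrow(regions)
  if (n == 0) abort("no regions to rank")
  ord <- order(regions$signal, regions$region_id %||% seq_len(n))
  s <- regions$signal[ord]
  if (n < 2 || diff(range(s)) == 0) {
    warn("all region signals identical: no super-enhancers called")
    curve <- tibble(rank = seq_len(n), signal = s,
                    scaled_rank = NA_real_, scaled_signal = NA_real_,
                    is_se = FALSE)
    return(structure(list(superenhancers = regions[0, ],
                          cutoff_signal = Inf, curve = curve),
                     class = "se_rank"))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  cut_idx <- which.min(y - x) # farthest below the slope-1 diagonal
  cutoff <- s[cut_idx]
  is_se <- s > cutoff
  curve <- tibble(rank = seq_len(n), signal = s,
                  scaled_rank = x, scaled_signal = y, is_se = is_se)
  ses <- regions[ord[is_se], , drop = FALSE]
  ses <- ses[order(-ses$signal), , drop = FALSE]
  structure(list(superenhancers = as_tibble(ses), cutoff_signal = cutoff,
                 curve = curve),
            class = "se_rank")
}

#' @export
print.se_rank <- function(x, ...) {
  cat(sprintf("<se_rank> %d/%d regions above cutoff signal %.4g\n",
              nrow(x$superenhancers), nrow(x$curve), x$cutoff_signal))
  invisible(x)
}

#' Promoter fraction of a set of constituent peaks
#'
#' A constituent counts as a promoter peak iff its interval is fully
#' contained in the TSS +/- `tss_window` region of some gene; overlap
#' without containment does not count. The +/- 2 kb window is closed at
#' both ends in genomic bp, i.e. `[tss - w, tss + w + 1)` in half-open
#' coordinates.
#'
#' @param constituents Data frame of constituent intervals (`chrom`,
#'   `start`, `end`, `peak_id`).
#' @param tss Data frame with `chrom` and `tss` (bp position) per gene.
#' @param tss_window Half-width of the promoter window in bp (default 2000).
#' @return Logical vector: is each constituent a promoter peak?
#' @export
is_promoter_peak <- function(constituents, tss, tss_window = 2000) {
  if (nrow(constituents) == 0) return(logical(0))
  if (is.null(tss) || nrow(tss) == 0) return(rep(FALSE, nrow(constituents)))
  win <- tibble(chrom = tss$chrom,
                start = pmax(0, tss$tss - tss_window),
                end = tss$tss + tss_window + 1)
  hits <- GenomicRanges::findOverlaps(as_granges0(constituents),
                                      as_granges0(win), type = "within")
  seq_len(nrow(constituents)) %in% S4Vectors::queryHits(hits)
}

#' Call super-enhancers at a reference stage
#'
#' Full ROSE-style call on the unified peak set: restrict to the peaks
#' present at the calling stage (unified membership), stitch within
#' `stitch_distance`, total the quantile-normalized RPM of constituents at
#' that stage, call SEs by the rank-curve elbow
#' ([se_rank_threshold()]), and drop SEs whose promoter-peak fraction is
#' >= `promoter_fraction_max`. Under the 50% rule an SE with 3 or 4
#' constituents may keep at most one promoter peak.
#'
#' @param unified A `unified_peaks` object.
#' @param signal A `signal_matrix` over the unified peaks (normally
#'   quantile-normalized).
#' @param tss TSS table (`gene_id`, `chrom`, `tss`, `strand`) for the
#'   promoter filter; `NULL` skips the filter.
#' @param calling_stage Stage label or index (1-based) at which SEs are
#'   called. Default: the last stage (activation analysis). Use the first
#'   stage for decommission analysis.
#' @param stitch_distance ROSE stitching distance in bp (default 12500).
#' @param tss_window Promoter half-window in bp (default 2000).
#' @param promoter_fraction_max SEs with promoter fraction >= this are
#'   removed (default 0.5).
#' @return A list of class `"se_call"`: `ses` (tibble `se_id`, `chrom`,
#'   `start`, `end`, `n_constituents`, `constituents`, `signal`,
#'   `promoter_fraction`, `calling_stage`), `cutoff_signal`, `curve`,
#'   `removed_promoter_heavy`, `calling_stage`, and the configuration.
#' @export
call_superenhancers <- function(unified, signal, tss = NULL,
                                calling_stage = NULL,
                                stitch_distance = 12500,
                                tss_window = 2000,
                                promoter_fraction_max = 0.5) {
  stages <- unified$stages
  calling_stage <- calling_stage %||% stages[length(stages)]
  if (is.numeric(calling_stage)) calling_stage <- stages[calling_stage]
  if (!calling_stage %in% stages) abort("unknown calling stage")

  present <- unique(unified$membership$peak_id[
    unified$membership$stage == calling_stage])
  stage_peaks <- unified$peaks[unified$peaks$peak_id %in% present, , drop = FALSE]
  regions <- stitch_peaks(stage_peaks, stitch_distance)

  sig <- signal_values(signal)[, calling_stage]
  regions$signal <- map_dbl(regions$constituents,
                            function(ids) sum(sig[ids]))
  ranked <- se_rank_threshold(regions)
  ses <- ranked$superenhancers

  if (nrow(ses) > 0) {
    pk <- unified$peaks
    ses$promoter_fraction <- map_dbl(ses$constituents, function(ids) {
      cons <- pk[match(ids, pk$peak_id), , drop = FALSE]
      if (is.null(tss)) return(0)
      mean(is_promoter_peak(cons, tss, tss_window))
    })
  } else {
    ses$promoter_fraction <- numeric(0)
  }
  keep <- ses$promoter_fraction < promoter_fraction_max
  removed <- ses[!keep, , drop = FALSE]
  ses <- ses[keep, , drop = FALSE]
  if (nrow(ses) > 0) {
    ses$se_id <- sprintf("se%04d", seq_len(nrow(ses)))
  } else {
    ses$se_id <- character(0)
  }
  ses$calling_stage <- calling_stage
  ses <- ses[, c("se_id", "chrom", "start", "end", "n_constituents",
                 "constituents", "signal", "promoter_fraction",
                 "calling_stage")]

  structure(
    list(ses = as_tibble(ses), cutoff_signal = ranked$cutoff_signal,
         curve = ranked$curve, removed_promoter_heavy = as_tibble(removed),
         calling_stage = calling_stage,
         config = list(stitch_distance = stitch_distance,
                       tss_window = tss_window,
                       promoter_fraction_max = promoter_fraction_max)),
    class = "se_call"
  )
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf(
    "<se_call> %d super-enhancers at stage %s (cutoff %.4g, %d promoter-heavy removed)\n",
    nrow(x$ses), x$calling_stage, x$cutoff_signal,
    nrow(x$removed_promoter_heavy)))
  invisible(x)
}
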