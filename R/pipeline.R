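# Map coordinate-keyed counts onto unified peak ids by interval overlap
# (a count record contributes to the unified peak containing its interval).
map_counts_to_unified <- function(counts, unified) {
  if ("peak_id" %in% names(counts)) return(counts)
  req <- c("chrom", "start", "end", "stage", "count")
  if (!all(req %in% names(counts))) {
    abort("counts need peak_id or chrom/start/end plus stage, count")
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(counts),
                                      as_granges0(unified$peaks),
                                      minoverlap = 1L)
  tibble(
    peak_id = unified$peaks$peak_id[S4Vectors::subjectHits(hits)],
    stage = as.character(counts$stage)[S4Vectors::queryHits(hits)],
    count = counts$count[S4Vectors::queryHits(hits)]
  ) |>
    group_by(.data$peak_id, .data$stage) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Run the full super-enhancer temporal pipeline
#'
#' Orchestrates the stages: unify per-stage peaks, build and
#' quantile-normalize the RPM matrix, call super-enhancers at the
#' reference stage, classify them into Con/TH/DN by consensus k-means,
#' assign target genes and compute expression metrics, time TH constituent
#' elements, and (when Hi-C inputs are present) derive insulation
#' boundaries, FIRE scores, and compartment categories. The run is
#' deterministic given identical inputs and `master_seed`.
#'
#' @param x An `se_bundle` (from [simulate_se_bundle()]) or a list with
#'   components `stages`, `peaks`, `counts`, `library_sizes`,
#'   `expression`, `tss`, and optionally `hic`, `blacklist`.
#' @param reference_stage `"last"` (activation analysis, default) or
#'   `"first"` (decommission analysis: SEs called in the starting cells).
#' @param master_seed Integer seed for all stochastic stages.
#' @param K,n_rounds,n_representatives Classification parameters.
#' @param target_window,rpkm_min,r_min Target-assignment thresholds.
#' @return A list of class `"se_pipeline"`: `unified`, `signal`
#'   (normalized), `se_call`, `classification`, `targets`, `metrics`,
#'   `metric_tests`, `timing`, `hic` (or `NULL`), and `manifest`.
#' @export
run_se_pipeline <- function(x, reference_stage = c("last", "first"),
                            master_seed = 1, K = 3, n_rounds = 100,
                            n_representatives = 4,
                            target_window = 1e5, rpkm_min = 2,
                            r_min = 0.75) {
  reference_stage <- match.arg(reference_stage)
  stages <- x$stages
  mode <- if (reference_stage == "last") "activation" else "decommission"

  peaks <- x$peaks
  if (!is.null(x$blacklist)) peaks <- filter_blacklist(peaks, x$blacklist)
  unified <- unify_peaks(peaks, stage_levels = stages)
  counts <- map_counts_to_unified(x$counts, unified)
  signal <- quantile_normalize(rpm_matrix(unified, counts, x$library_sizes))

  calling_stage <- if (reference_stage == "last") stages[length(stages)]
                   else stages[1]
  secall <- call_superenhancers(unified, signal, tss = x$tss,
                                calling_stage = calling_stage)
  classification <- classify_se(secall, signal, K = K, n_rounds = n_rounds,
                                master_seed = master_seed,
                                n_representatives = n_representatives,
                                mode = mode)

  targets <- assign_targets(secall$ses, signal, x$expression, x$tss,
                            window = target_window, rpkm_min = rpkm_min,
                            r_min = r_min)
  focal <- if (reference_stage == "last") length(stages) else 1L
  metrics <- se_target_metrics(targets, classification, x$expression,
                               secall$ses, x$tss, focal_stage = focal)
  metric_tests <- if (length(unique(metrics$label)) >= 2) {
    group_compare(split(metrics$fold_change, metrics$label))
  } else {
    NULL
  }
  timing <- element_timing_table(secall$ses, signal,
                                 labels = classification$classification,
                                 subtype = "TH")

  hic_out <- NULL
  if (!is.null(x$hic)) {
    ref_hic <- if (reference_stage == "last") length(stages) else 1L
    insul <- insulation_scores(x$hic$tad[[ref_hic]])
    insul$boundaries$chrom <- x$hic$tad[[ref_hic]]$chrom
    fires <- fire_scores(x$hic$fire)
    comps <- categorize_compartments(x$hic$pc1_first, x$hic$pc1_last)
    hic_out <- list(insulation = insul, fires = fires, compartments = comps)
  } else {
    message("no Hi-C inputs: architecture stages skipped")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sedyn")),
    master_seed = master_seed,
    reference_stage = reference_stage,
    stages = stages,
    n_input_peaks = nrow(peaks),
    n_unified_peaks = nrow(unified$peaks),
    n_superenhancers = nrow(secall$ses),
    cutoff_signal = secall$cutoff_signal,
    class_counts = as.list(table(classification$classification$label)),
    n_targets = nrow(targets),
    config = list(K = K, n_rounds = n_rounds,
                  n_representatives = n_representatives,
                  target_window = target_window, rpkm_min = rpkm_min,
                  r_min = r_min)
  )

  structure(
    list(unified = unified, signal = signal, se_call = secall,
         classification = classification, targets = targets,
         metrics = metrics, metric_tests = metric_tests, timing = timing,
         hic = hic_out, manifest = manifest),
    class = "se_pipeline")
}

#' @export
print.se_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<se_pipeline> %s analysis, seed %d\n",
              ifelse(m$reference_stage == "last", "activation",
                     "decommission"), m$master_seed))
  cat(sprintf("  %d unified peaks -> %d SEs (cutoff %.4g)\n",
              m$n_unified_peaks, m$n_superenhancers, m$cutoff_signal))
  cc <- unlist(m$class_counts)
  cat("  classes:", paste(names(cc), cc, sep = "=", collapse = " "), "\n")
  cat(sprintf("  %d target-gene assignments\n", m$n_targets))
  invisible(x)
}
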