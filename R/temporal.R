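#' Relative standard deviation of a signal profile
#'
#' RSD = population standard deviation / mean, the statistic used to sort a
#' super-enhancer's constituent elements by temporal variability before
#' vector standardization. An all-zero profile has RSD 0 by convention.
#'
#' @param values Nonnegative numeric vector (signal across stages).
#' @return The RSD as a single double.
#' @examples
#' rsd(c(1, 3)) # pop sd 1 / mean 2 = 0.5
#' @export
rsd <- function(values) {
  if (any(values < 0)) abort("rsd() requires nonnegative values")
  m <- mean(values)
  if (m == 0) return(0)
  pop_sd <- sqrt(mean((values - m)^2))
  pop_sd / m
}

# Extract the constituents x stages submatrix of one SE.
se_submatrix <- function(constituent_ids, signal) {
  m <- signal_values(signal)
  found <- constituent_ids %in% rownames(m)
  if (!all(found)) {
    abort(paste0("constituents missing from signal matrix: ",
                 paste(constituent_ids[!found], collapse = ", ")))
  }
  m[constituent_ids, , drop = FALSE]
}

#' Standardize one SE into a fixed-length temporal vector
#'
#' Super-enhancers have varying numbers of constituents, so their raw
#' signal submatrices have varying dimension. This standardizes each SE to
#' `n_representatives` "representative enhancers": constituents are sorted
#' ascending by RSD (ties broken by id), and for each stage the signal
#' profile along the sorted-constituent axis is linearly interpolated at
#' fractions `{0, 1/3, 2/3, 1}` (for 4 representatives) of the axis. The
#' interpolated series are concatenated representative-major into one
#' vector of length `n_representatives * T`.
#'
#' With exactly `n_representatives` constituents the representatives equal
#' the RSD-sorted constituent profiles verbatim; a single-constituent SE
#' repeats its profile in every representative.
#'
#' @param sub Numeric matrix, constituents x stages, rownames = constituent
#'   ids, values >= 0 (quantile-normalized RPM).
#' @param n_representatives Number of representatives (default 4;
#'   alternatives 5 or 6 for robustness checks).
#' @param per_stage_sorted If `TRUE`, use the alternative reading in which
#'   each stage's values are sorted independently (per-stage order
#'   statistics) instead of following one RSD-sorted constituent axis.
#'   Default `FALSE`.
#' @param normalize Divide the vector by its maximum (max-normalization,
#'   mirroring relative-signal heatmaps). All-zero vectors are left as is.
#' @return Numeric vector of length `n_representatives * ncol(sub)` with
#'   names `rep<k>_<stage>`.
#' @export
build_se_vector <- function(sub, n_representatives = 4,
                            per_stage_sorted = FALSE, normalize = TRUE) {
  if (is.null(dim(sub)) || ncol(sub) < 1) abort("sub must be a matrix")
  if (any(sub < 0)) abort("signal values must be >= 0")
  n <- nrow(sub)
  stages <- colnames(sub) %||% paste0("s", seq_len(ncol(sub)))
  ids <- rownames(sub) %||% as.character(seq_len(n))

  if (!per_stage_sorted) {
    rsds <- apply(sub, 1, rsd)
    ord <- order(rsds, ids)
    sorted <- sub[ord, , drop = FALSE]
  } else {
    sorted <- apply(sub, 2, sort)
    if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = 1)
  }

  fracs <- seq(0, 1, length.out = n_representatives)
  reps <- matrix(0, n_representatives, ncol(sub))
  for (s in seq_len(ncol(sub))) {
    p <- sorted[, s]
    if (n == 1) {
      reps[, s] <- rep(p, n_representatives)
    } else {
      reps[, s] <- approx(x = seq_len(n) - 1, y = p, xout = fracs * (n - 1),
                          method = "linear")$y
    }
  }
  v <- as.vector(t(reps)) # representative-major: rep1 stages, rep2 stages, ...
  names(v) <- paste0("rep", rep(seq_len(n_representatives), each = ncol(sub)),
                     "_", rep(stages, n_representatives))
  if (normalize && max(v) > 0) v <- v / max(v)
  v
}

#' Build the SE-by-feature vector matrix for a set of super-enhancers
#'
#' @param ses SE tibble (from [call_superenhancers()]) with `se_id` and
#'   `constituents`.
#' @param signal A `signal_matrix` covering all constituents.
#' @inheritParams build_se_vector
#' @return Numeric matrix, one row per SE (rownames = `se_id`), with
#'   `n_representatives * T` columns.
#' @export
se_vector_matrix <- function(ses, signal, n_representatives = 4,
                             per_stage_sorted = FALSE, normalize = TRUE) {
  if (nrow(ses) == 0) abort("no super-enhancers")
  rows <- map(ses$constituents, function(ids) {
    build_se_vector(se_submatrix(ids, signal),
                    n_representatives = n_representatives,
                    per_stage_sorted = per_stage_sorted,
                    normalize = normalize)
  })
  vm <- do.call(rbind, rows)
  rownames(vm) <- ses$se_id
  vm
}

#' Consensus k-means clustering of SE temporal vectors
#'
#' Runs `n_rounds` k-means clusterings (Euclidean distance, `K` clusters,
#' random initial centers) seeded from a deterministic stream derived from
#' `master_seed`, accumulates the co-association matrix `A[i, j]` =
#' fraction of rounds placing SEs i and j in the same cluster, and cuts an
#' average-linkage hierarchical clustering of `1 - A` into `K` groups. The
#' result is bit-reproducible given `master_seed` and invariant to the
#' input row order (rows are processed in a canonical lexicographic order
#' internally).
#'
#' @param vectors Numeric matrix, one SE per row (rownames = SE ids).
#' @param K Number of clusters (default 3).
#' @param n_rounds Number of k-means repetitions (default 100).
#' @param master_seed Integer master seed (default 1).
#' @return A list of class `"se_consensus"`: `assignment` (tibble `se_id`,
#'   `cluster`), `coassociation` (n x n matrix), `K`, `n_rounds`,
#'   `master_seed`.
#' @export
consensus_kmeans <- function(vectors, K = 3, n_rounds = 100, master_seed = 1) {
  n <- nrow(vectors)
  if (n < K) abort("fewer vectors than clusters")
  ids <- rownames(vectors) %||% as.character(seq_len(n))

  # canonical row order -> partition independent of input ordering
  canon <- do.call(order, c(as.data.frame(vectors), list(ids)))
  vm <- vectors[canon, , drop = FALSE]

  seeds <- derive_seeds(master_seed, n_rounds)
  co <- matrix(0, n, n)
  for (r in seq_len(n_rounds)) {
    cl <- with_seed(seeds[r],
                    kmeans(vm, centers = K, nstart = 1, iter.max = 100))
    same <- outer(cl$cluster, cl$cluster, `==`)
    co <- co + same
  }
  co <- co / n_rounds
  hc <- hclust(as.dist(1 - co), method = "average")
  grp_canon <- cutree(hc, k = K)

  assignment <- integer(n)
  assignment[canon] <- grp_canon
  co_orig <- matrix(0, n, n)
  co_orig[canon, canon] <- co
  dimnames(co_orig) <- list(ids, ids)

  structure(
    list(assignment = tibble(se_id = ids, cluster = assignment),
         coassociation = co_orig, K = K, n_rounds = n_rounds,
         master_seed = master_seed),
    class = "se_consensus"
  )
}

#' @export
print.se_consensus <- function(x, ...) {
  cat(sprintf("<se_consensus> %d SEs, K = %d, %d rounds (seed %d)\n",
              nrow(x$assignment), x$K, x$n_rounds, x$master_seed))
  print(table(x$assignment$cluster))
  invisible(x)
}

# Per-SE mean trajectory (mean over representatives at each stage) from a
# vector matrix laid out representative-major.
se_mean_trajectories <- function(vectors, n_stages) {
  n_rep <- ncol(vectors) / n_stages
  if (n_rep != round(n_rep)) abort("vector length is not a multiple of T")
  sapply(seq_len(n_stages), function(s) {
    rowMeans(vectors[, s + (seq_len(n_rep) - 1) * n_stages, drop = FALSE])
  })
}

#' Name consensus clusters as Con / TH / DN subtypes
#'
#' For each cluster, the mean max-normalized SE trajectory m(t) is computed
#' (averaging the representatives per stage, then normalizing the cluster
#' mean to max 1) and clusters are ordered by mean signal over stages
#' (area under m(t)): the highest is conserved (Con, persistently high
#' signal), the lowest is de novo (DN, signal confined to the extreme of
#' the course), and the middle is temporally hierarchical (TH, staggered
#' gain). Under decommission analysis (reference stage = first) the same
#' ordering applies: DN SEs lose their signal fastest and again have the
#' lowest area.
#'
#' @param consensus An `"se_consensus"` object (K must be 3 for Con/TH/DN
#'   names; other K get generic `cluster_<k>` names with AUC ranks).
#' @param vectors The vector matrix used for clustering.
#' @param n_stages Number of stages T.
#' @param mode `"activation"` or `"decommission"` (recorded; the AUC
#'   ordering rule is shared).
#' @return A list of class `"se_labeling"`: `labels` (tibble `cluster`,
#'   `label`, `auc`, `trend`), `cluster_to_label` (named character),
#'   `mean_trajectories` (tibble `cluster`, `label`, `stage_index`,
#'   `mean_signal`), `mode`.
#' @export
label_clusters <- function(consensus, vectors, n_stages,
                           mode = c("activation", "decommission")) {
  mode <- match.arg(mode)
  assign <- consensus$assignment
  traj <- se_mean_trajectories(vectors[assign$se_id, , drop = FALSE], n_stages)
  mx <- apply(traj, 1, max)
  traj_norm <- traj / ifelse(mx > 0, mx, 1)

  cl_levels <- sort(unique(assign$cluster))
  cl_means <- t(sapply(cl_levels, function(k) {
    colMeans(traj_norm[assign$cluster == k, , drop = FALSE])
  }))
  cl_means <- cl_means / apply(cl_means, 1, max)
  if (nrow(unique(round(cl_means, 10))) < length(cl_levels)) {
    abort("clusters indistinguishable")
  }
  auc <- rowMeans(cl_means)
  trend <- cl_means[, n_stages] - cl_means[, 1]

  rk <- rank(-auc, ties.method = "first") # 1 = highest AUC
  if (consensus$K == 3 && length(cl_levels) == 3) {
    label <- c("Con", "TH", "DN")[rk]
  } else {
    label <- paste0("cluster_", cl_levels - 1)
  }
  labels <- tibble(cluster = cl_levels, label = label, auc = auc,
                   auc_rank = rk, trend = trend)
  mean_traj <- tibble(
    cluster = rep(cl_levels, each = n_stages),
    label = rep(label, each = n_stages),
    stage_index = rep(seq_len(n_stages) - 1L, length(cl_levels)),
    mean_signal = as.vector(t(cl_means))
  )
  structure(
    list(labels = labels,
         cluster_to_label = setNames(label, cl_levels),
         mean_trajectories = mean_traj, mode = mode),
    class = "se_labeling"
  )
}

#' Classify super-enhancers into temporal subtypes
#'
#' End-to-end wrapper for the core method: build fixed-length temporal
#' vectors for each SE ([build_se_vector()]), cluster them by consensus
#' k-means ([consensus_kmeans()]), and name clusters Con / TH / DN by their
#' mean-trajectory area ([label_clusters()]).
#'
#' @param ses SE tibble from [call_superenhancers()] (the `$ses` element)
#'   or an `"se_call"` object.
#' @param signal The quantile-normalized `signal_matrix`.
#' @param K,n_rounds,master_seed Consensus k-means parameters.
#' @param n_representatives Representatives per SE (default 4).
#' @param per_stage_sorted,normalize Passed to [build_se_vector()].
#' @param mode `"activation"` (SEs called at the last stage) or
#'   `"decommission"` (called at the first stage).
#' @return A list of class `"se_classification"`: `classification` (tibble
#'   `se_id`, `cluster`, `label`), `consensus`, `labeling`, `vectors`,
#'   `n_stages`, plus the configuration.
#' @export
classify_se <- function(ses, signal, K = 3, n_rounds = 100, master_seed = 1,
                        n_representatives = 4, per_stage_sorted = FALSE,
                        normalize = TRUE,
                        mode = c("activation", "decommission")) {
  mode <- match.arg(mode)
  if (inherits(ses, "se_call")) ses <- ses$ses
  stages <- attr(signal, "stages")
  vm <- se_vector_matrix(ses, signal, n_representatives = n_representatives,
                         per_stage_sorted = per_stage_sorted,
                         normalize = normalize)
  cons <- consensus_kmeans(vm, K = K, n_rounds = n_rounds,
                           master_seed = master_seed)
  labeling <- label_clusters(cons, vm, n_stages = length(stages), mode = mode)
  classification <- cons$assignment |>
    mutate(label = unname(labeling$cluster_to_label[as.character(.data$cluster)]))
  structure(
    list(classification = classification, consensus = cons,
         labeling = labeling, vectors = vm, n_stages = length(stages),
         stages = stages,
         config = list(K = K, n_rounds = n_rounds, master_seed = master_seed,
                       n_representatives = n_representatives,
                       per_stage_sorted = per_stage_sorted,
                       normalize = normalize, mode = mode)),
    class = "se_classification"
  )
}

#' @export
print.se_classification <- function(x, ...) {
  cat(sprintf("<se_classification> %d SEs, K = %d (%s mode)\n",
              nrow(x$classification), x$config$K, x$config$mode))
  print(table(x$classification$label))
  invisible(x)
}

#' Time the commission of constituent elements
#'
#' For each constituent element of a super-enhancer, the commission stage
#' is the first stage at which its signal reaches `alpha` times its own
#' maximum over the course. Elements are classed `early` when commissioned
#' at or before `early_max_stage` (default the first stage), `late` when
#' commissioned at or after `late_min_stage` (default stage T-2, 0-based),
#' and `intermediate` otherwise. All-zero elements have no defined timing
#' and are flagged.
#'
#' @param sub Constituents x stages signal matrix (rownames = ids).
#' @param alpha Activation fraction in (0, 1] (default 0.5).
#' @param early_max_stage Latest 0-based commission stage still called
#'   early (default 0).
#' @param late_min_stage Earliest 0-based commission stage called late
#'   (default `ncol(sub) - 2`).
#' @return Tibble `constituent_id`, `commission_stage` (0-based, `NA` when
#'   undefined), `timing_class` (`early` / `intermediate` / `late` /
#'   `undefined`).
#' @export
classify_element_timing <- function(sub, alpha = 0.5, early_max_stage = 0,
                                    late_min_stage = ncol(sub) - 2) {
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  ids <- rownames(sub) %||% as.character(seq_len(nrow(sub)))
  res <- map(seq_len(nrow(sub)), function(i) {
    p <- sub[i, ]
    if (max(p) == 0) {
      return(tibble(constituent_id = ids[i], commission_stage = NA_integer_,
                    timing_class = "undefined"))
    }
    cs <- unname(which(p >= alpha * max(p))[1]) - 1L
    cls <- if (cs <= early_max_stage) "early"
           else if (cs >= late_min_stage) "late"
           else "intermediate"
    tibble(constituent_id = ids[i], commission_stage = cs, timing_class = cls)
  })
  bind_rows(res)
}

#' Constituent timing for a classified SE set
#'
#' Applies [classify_element_timing()] to every SE (typically restricted to
#' the TH subtype, whose elements commission at staggered stages) and
#' returns one row per constituent.
#'
#' @param ses SE tibble with `se_id` and `constituents`.
#' @param signal A `signal_matrix`.
#' @param labels Optional tibble `se_id`, `label` to restrict by subtype.
#' @param subtype Subtype to keep when `labels` given (default `"TH"`).
#' @inheritParams classify_element_timing
#' @return Tibble `se_id`, `constituent_id`, `commission_stage`,
#'   `timing_class`.
#' @export
element_timing_table <- function(ses, signal, labels = NULL, subtype = "TH",
                                 alpha = 0.5, early_max_stage = 0,
                                 late_min_stage = NULL) {
  if (!is.null(labels)) {
    keep <- labels$se_id[labels$label == subtype]
    ses <- ses[ses$se_id %in% keep, , drop = FALSE]
  }
  n_stages <- length(attr(signal, "stages"))
  late_min_stage <- late_min_stage %||% (n_stages - 2)
  out <- map2(ses$se_id, ses$constituents, function(id, cons) {
    tm <- classify_element_timing(se_submatrix(cons, signal), alpha = alpha,
                                  early_max_stage = early_max_stage,
                                  late_min_stage = late_min_stage)
    tm$se_id <- id
    tm
  })
  bind_rows(out)[, c("se_id", "constituent_id", "commission_stage",
                     "timing_class")]
}
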