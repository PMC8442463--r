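#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a super-enhancer classification
#'
#' One row per super-enhancer with its consensus cluster and subtype
#' label.
#'
#' @param x An `se_classification`.
#' @param ... Unused.
#' @return Tibble `se_id`, `cluster`, `label`.
#' @method tidy se_classification
#' @export
tidy.se_classification <- function(x, ...) {
  as_tibble(x$classification)
}

#' One-row summary of a super-enhancer classification
#'
#' @param x An `se_classification`.
#' @param ... Unused.
#' @return Tibble with `n_se`, `k`, `n_rounds`, `master_seed`, per-class
#'   counts (`n_con`, `n_th`, `n_dn` when K = 3), and
#'   `mean_coassociation` (mean within-cluster co-association, a
#'   stability summary in \[0, 1\]).
#' @method glance se_classification
#' @export
glance.se_classification <- function(x, ...) {
  cl <- x$classification
  co <- x$consensus$coassociation
  within <- outer(cl$cluster, cl$cluster, `==`)
  diag(within) <- NA
  out <- tibble(
    n_se = nrow(cl), k = x$config$K, n_rounds = x$config$n_rounds,
    master_seed = x$config$master_seed,
    mean_coassociation = mean(co[which(within)], na.rm = TRUE)
  )
  if (x$config$K == 3) {
    out$n_con <- sum(cl$label == "Con")
    out$n_th <- sum(cl$label == "TH")
    out$n_dn <- sum(cl$label == "DN")
  }
  out
}

#' Tidy a super-enhancer call
#'
#' @param x An `se_call`.
#' @param ... Unused.
#' @return The SE tibble (`se_id`, coordinates, `n_constituents`,
#'   `signal`, `promoter_fraction`), without the list column.
#' @method tidy se_call
#' @export
tidy.se_call <- function(x, ...) {
  select(x$ses, -"constituents")
}

#' One-row summary of a super-enhancer call
#'
#' @param x An `se_call`.
#' @param ... Unused.
#' @return Tibble `n_regions`, `n_superenhancers`, `cutoff_signal`,
#'   `n_promoter_heavy_removed`, `calling_stage`.
#' @method glance se_call
#' @export
glance.se_call <- function(x, ...) {
  tibble(n_regions = nrow(x$curve),
         n_superenhancers = nrow(x$ses),
         cutoff_signal = x$cutoff_signal,
         n_promoter_heavy_removed = nrow(x$removed_promoter_heavy),
         calling_stage = x$calling_stage)
}
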