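#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_vline geom_hline geom_tile labs theme_minimal facet_wrap
#'   scale_color_brewer
#' @export
ggplot2::autoplot

#' Plot the SE rank curve (hockey-stick plot)
#'
#' Signal-versus-rank curve of stitched regions with the elbow cutoff;
#' regions above the cutoff are the called super-enhancers.
#'
#' @param object An `se_rank` (or `se_call`, whose curve is used).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot se_rank
#' @export
autoplot.se_rank <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$rank, y = .data$signal,
                           color = .data$is_se)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = object$cutoff_signal, linetype = "dashed") +
    labs(x = "region rank (ascending signal)", y = "total H3K27ac signal (RPM)",
         color = "super-enhancer",
         title = sprintf("%d super-enhancers above cutoff %.3g",
                         sum(object$curve$is_se), object$cutoff_signal)) +
    theme_minimal()
}

#' @rdname autoplot.se_rank
#' @method autoplot se_call
#' @export
autoplot.se_call <- function(object, ...) {
  autoplot.se_rank(structure(list(curve = object$curve,
                                  cutoff_signal = object$cutoff_signal),
                             class = "se_rank"))
}

#' Plot cluster mean trajectories of a classification
#'
#' Average max-normalized H3K27ac profile per subtype across stages — the
#' conserved subtype stays near 1 throughout, the temporally hierarchical
#' subtype rises gradually, and the de novo subtype rises late (mirrored
#' for decommission analyses).
#'
#' @param object An `se_classification`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot se_classification
#' @export
autoplot.se_classification <- function(object, ...) {
  tr <- object$labeling$mean_trajectories
  ggplot(tr, aes(x = .data$stage_index, y = .data$mean_signal,
                 color = .data$label)) +
    geom_line(linewidth = 1) + geom_point() +
    scale_color_brewer(palette = "Set1") +
    labs(x = "stage", y = "mean relative H3K27ac signal",
         color = "SE subtype") +
    theme_minimal()
}

#' Plot an insulation profile with its TAD boundaries
#'
#' @param object An `insulation_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot insulation_profile
#' @export
autoplot.insulation_profile <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$bin, y = .data$score)) +
    geom_line(na.rm = TRUE) +
    geom_vline(xintercept = object$boundaries$bin, color = "red",
               linetype = "dotted") +
    labs(x = sprintf("bin (%d kb)", object$resolution / 1000),
         y = "insulation score (log2 ratio)",
         title = sprintf("%d TAD boundaries", nrow(object$boundaries))) +
    theme_minimal()
}

#' Heatmap of per-SE temporal vectors ordered by subtype
#'
#' Displays each SE's fixed-length vector (representatives x stages) as a
#' row, grouped by subtype.
#'
#' @param classification An `se_classification`.
#' @return A ggplot.
#' @export
plot_se_vectors <- function(classification) {
  cl <- classification$classification
  vm <- classification$vectors[cl$se_id, , drop = FALSE]
  ord <- order(match(cl$label, c("Con", "TH", "DN")), cl$se_id)
  long <- tibble(
    se = rep(seq_along(ord), ncol(vm)),
    feature = rep(seq_len(ncol(vm)), each = length(ord)),
    value = as.vector(vm[ord, ]),
    label = rep(cl$label[ord], ncol(vm))
  )
  ggplot(long, aes(x = .data$feature, y = .data$se, fill = .data$value)) +
    geom_tile() +
    facet_wrap(~label, ncol = 1, scales = "free_y") +
    labs(x = "representative x stage feature", y = "super-enhancer",
         fill = "relative\nsignal") +
    theme_minimal()
}
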