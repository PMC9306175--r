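#' @title Plot helpers
#' @description ggplot2-based displays for the main result types: similarity
#'   heatmaps, stability (scree-style) curves and chain traces.
#' @name plots
NULL

cm_heatmap <- function(cm, order_items = TRUE) {
  n <- nrow(cm)
  ord <- seq_len(n)
  if (order_items && n > 2) {
    ord <- hclust(stats::as.dist(1 - unclass(cm)), method = "average")$order
  }
  items <- rownames(cm) %||% as.character(seq_len(n))
  df <- tibble::tibble(
    row = factor(rep(items[ord], times = n), levels = items[ord]),
    col = factor(rep(items[ord], each = n), levels = items[ord]),
    proportion = as.vector(unclass(cm)[ord, ord])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-clustering") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @rdname plots
#' @param object A `consensus_matrix`, `consensus_clustering`,
#'   `consensus_grid` or `mcmc_chain`.
#' @param ... Unused.
#' @export
autoplot.consensus_matrix <- function(object, ...) cm_heatmap(object)

#' @rdname plots
#' @export
autoplot.consensus_clustering <- function(object, ...) {
  cm_heatmap(object$consensus)
}

#' @rdname plots
#' @export
autoplot.consensus_grid <- function(object, ...) {
  plot_stability_curves(stability_curves(object))
}

#' @rdname plots
#' @export
autoplot.mcmc_chain <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line(colour = "#08519c") +
    ggplot2::labs(x = "sweep", y = "log-likelihood") +
    ggplot2::theme_minimal()
}

#' Elbow-style plot of ensemble stability curves
#'
#' @param curves A tibble from [stability_curves()].
#' @return A ggplot object: sequential mean absolute consensus-matrix
#'   differences against depth (one line per width) and against width (one
#'   line per depth).
#' @export
plot_stability_curves <- function(curves) {
  df <- dplyr::mutate(
    curves,
    x = ifelse(.data$curve == "depth", .data$depth, .data$width),
    series = ifelse(.data$curve == "depth",
                    paste0("W = ", .data$width),
                    paste0("D = ", .data$depth))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mad,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~curve, scales = "free_x") +
    ggplot2::labs(x = "grid point (log scale)",
                  y = "mean |CM difference|", colour = NULL) +
    ggplot2::theme_minimal()
}
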