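#' Plot an embedding coloured by modality and cell type
#'
#' Reduces the embedding to 2-D with [umap2d()] (skipped when it already
#' has exactly two coordinate columns) and draws side-by-side panels
#' coloured by modality and, when present, by cell-type label.
#'
#' @param object An embedding tibble.
#' @param seed Seed passed to [umap2d()].
#' @param point_size Point size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modalign_embedding <- function(object, seed = 0,
                                        point_size = 0.6, ...) {
  X <- embedding_dims(object)
  coords <- if (ncol(X) == 2) X else umap2d(object, seed = seed)
  df <- tibble::tibble(x = coords[, 1], y = coords[, 2],
                       modality = object$modality, label = object$label)
  long <- dplyr::bind_rows(
    dplyr::mutate(df, facet = "modality", colour = .data$modality),
    if (!all(is.na(df$label))) {
      dplyr::mutate(df, facet = "cell type", colour = .data$label)
    })
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y,
                                     colour = .data$colour)) +
    ggplot2::geom_point(size = point_size, alpha = 0.7) +
    ggplot2::facet_wrap(~facet) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot training loss curves
#'
#' @param object A `modalign_fit`.
#' @param terms Which loss terms to draw (defaults to all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modalign_fit <- function(object, terms = NULL, ...) {
  long <- tidy(object)
  if (!is.null(terms)) long <- dplyr::filter(long, .data$term %in% terms)
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "mean loss per step") +
    ggplot2::theme_minimal()
}

#' Scatter of the benchmark plane: modality vs cell-type silhouette
#'
#' One point per method; ideal integrations sit in the top-right corner.
#'
#' @param reports A `metrics_report` tibble (one row per method).
#' @return A ggplot object.
#' @export
plot_metric_plane <- function(reports) {
  ggplot2::ggplot(reports,
                  ggplot2::aes(.data$S_modality, .data$S_celltype,
                               label = .data$method)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "modality silhouette (mixing)",
                  y = "cell-type silhouette (structure)") +
    ggplot2::theme_minimal()
}
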