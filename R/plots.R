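#' Plot an RDM as a distance heatmap
#'
#' @param object An [rdm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdm <- function(object, ...) {
  df <- tidyr::expand_grid(
    condition_a = factor(rownames(object), levels = rownames(object)),
    condition_b = factor(rownames(object), levels = rownames(object))
  )
  df$distance <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition_b, .data$condition_a,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "crossnobis\ndistance") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Scatter of an index against prosthesis usage
#'
#' @param indices Output of [compute_similarity_indices()] (users only are
#'   plotted; controls have no usage score).
#' @param index Column to plot on the y axis.
#' @return A ggplot object with a linear fit.
#' @export
plot_index_vs_usage <- function(indices, index = "prosthesis_similarity_std") {
  df <- indices[indices$group == "user" & !is.na(indices$usage_score), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$usage_score, .data[[index]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "grey30") +
    ggplot2::labs(x = "prosthesis usage score", y = index) +
    ggplot2::theme_classic()
}

#' Plot a group dendrogram
#'
#' @param dendro A [linkage_dendrogram()] result.
#' @param main Plot title.
#' @return Invisibly, the `hclust` object (base graphics plot).
#' @export
plot_dendrogram <- function(dendro, main = "") {
  stopifnot(inherits(dendro, "prosrsa_dendrogram"))
  plot(dendro$hclust, main = main, xlab = "", sub = "", ylab = "distance")
  invisible(dendro$hclust)
}
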