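#' Two-class KDE plot with the intersection threshold
#'
#' Draws the positive- and negative-class score densities and marks the
#' decision threshold as a dashed vertical line — the plot from which a
#' KDE-intersection classifier is read.
#'
#' @param pos_values,neg_values Class score vectors.
#' @param model Optional `threshold_model` (computed from the values via
#'   [intersection_threshold()] when omitted).
#' @param labels Length-2 class labels for the legend.
#' @param ... Passed to [kde_density()].
#' @return A ggplot object.
#' @export
plot_kde_threshold <- function(pos_values, neg_values, model = NULL,
                               labels = c("positive", "negative"), ...) {
  model <- model %||% intersection_threshold(pos_values, neg_values, ...)
  curves <- dplyr::bind_rows(
    dplyr::mutate(kde_density(pos_values, ...), class = labels[1]),
    dplyr::mutate(kde_density(neg_values, ...), class = labels[2])
  )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$grid, y = .data$density,
                                       colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = model$threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = model$domain, y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Fingerprint similarity heatmap in clustered leaf order
#'
#' Renders a Tanimoto similarity matrix with rows and columns ordered by
#' the hierarchical clustering of the fingerprints, the standard view for
#' comparing consensus binding modes across a ligand panel.
#'
#' @param sim Similarity matrix from [tanimoto_matrix()].
#' @param hc Optional [stats::hclust]; computed via
#'   [cluster_fingerprints()] when omitted.
#' @param linkage Linkage used when `hc` is computed here.
#' @return A ggplot object.
#' @export
plot_similarity_heatmap <- function(sim, hc = NULL,
                                    linkage = c("average", "complete", "single")) {
  hc <- hc %||% cluster_fingerprints(sim, linkage = rlang::arg_match(linkage))
  ord <- rownames(sim)[hc$order]
  long <- as_tibble(as.data.frame(as.table(unclass(sim)),
                                  stringsAsFactors = FALSE))
  names(long) <- c("ligand_a", "ligand_b", "tanimoto")
  long$ligand_a <- factor(long$ligand_a, levels = ord)
  long$ligand_b <- factor(long$ligand_b, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ligand_a, y = .data$ligand_b,
                                     fill = .data$tanimoto)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Tanimoto") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
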