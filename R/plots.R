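#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a 3x3 confusion matrix as a tile heatmap
#'
#' @param object A `confusion_matrix3`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confusion_matrix3 <- function(object, ...) {
  df <- tidy(object)
  df$truth <- factor(df$truth, levels = rev(phenotype_levels()))
  df$assigned <- factor(df$assigned, levels = phenotype_levels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$assigned, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2b6cb0") +
    ggplot2::labs(x = "Assigned phenotype", y = "Stained phenotype") +
    ggplot2::theme_minimal()
}

#' Heatmap of classifier centroid means
#'
#' @param object A `spatial_classifier`.
#' @param ... Unused.
#' @return A ggplot with genes ordered by signature phenotype.
#' @export
autoplot.spatial_classifier <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$genes,
    dplyr::all_of(paste0("mean_", phenotype_levels())),
    names_to = "phenotype", values_to = "mean_log2", names_prefix = "mean_")
  df$gene_id <- factor(df$gene_id, levels = rev(object$genes$gene_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype, y = .data$gene_id,
                                   fill = .data$mean_log2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b",
                                  midpoint = mean(df$mean_log2)) +
    ggplot2::labs(x = "Phenotype centroid", y = NULL,
                  fill = "mean log2") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a stamp-based cell pattern
#'
#' One panel per stamp (faceted by region), points coloured by marker; the
#' visual counterpart of the density summaries.
#'
#' @param cells Cell table tibble.
#' @param sample One sample id to plot (defaults to the first).
#' @return A ggplot.
#' @export
plot_cell_pattern <- function(cells, sample = NULL) {
  check_cells(cells)
  sample <- sample %||% cells$sample_id[1]
  df <- cells[cells$sample_id == sample, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   colour = .data$marker)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::facet_wrap(~ region + stamp_id, nrow = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", title = sample) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 6))
}

#' Bar plot of per-region cell densities
#'
#' @param densities Output of [compute_densities()].
#' @return A ggplot of density per marker, dodged by region, faceted by
#'   sample.
#' @export
plot_densities <- function(densities) {
  check_columns(densities, c("sample_id", "marker", "region",
                             "density_per_mm2"), "densities")
  ggplot2::ggplot(densities,
                  ggplot2::aes(x = .data$marker, y = .data$density_per_mm2,
                               fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ sample_id) +
    ggplot2::labs(x = NULL, y = "cells / mm²") +
    ggplot2::theme_minimal()
}
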