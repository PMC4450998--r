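#' Mean versus relative divergence
#'
#' The characteristic mean-CV cloud: lowly expressed genes show high
#' relative divergence (sampling noise dominates), well-expressed genes
#' plateau near their biological CV.
#'
#' @param object A [divergence_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.divergence_table <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$cv), .data$mean > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$cv)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean expression (rpkm)",
                  y = "relative divergence (sd / mean)") +
    ggplot2::theme_minimal()
}

#' Saturation curve of the relative divergence estimate
#'
#' @param object A [depth_curve()] or [cell_count_curve()] result.
#' @param ... Unused.
#' @return A ggplot: one line per expression stratum over the grid, ribbon
#'   showing the replicate spread.
#' @export
autoplot.saturation_curve <- function(object, ...) {
  axis <- attr(object, "axis")
  xvar <- if (axis == "depth") "depth" else "n_cells"
  xlab <- if (axis == "depth") "tags per cell" else "number of cells"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]], y = .data$mean_cv,
                                       colour = .data$stratum)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_cv - .data$sd_cv,
                                      ymax = .data$mean_cv + .data$sd_cv,
                                      fill = .data$stratum),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = xlab, y = "mean relative divergence",
                  colour = "expression stratum", fill = "expression stratum") +
    ggplot2::theme_minimal()
}

#' Fold-change plane of a condition comparison
#'
#' Scatter of log2 mean fold change against log2 relative-divergence fold
#' change; dashed lines mark no change.
#'
#' @param object A [compare_conditions()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.response_comparison <- function(object, ...) {
  df <- dplyr::filter(object, .data$class != "ineligible",
                      is.finite(.data$cv_fc))
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$mean_fc),
                                   y = log2(.data$cv_fc),
                                   colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::labs(x = "log2 fold change of mean expression",
                  y = "log2 fold change of relative divergence") +
    ggplot2::theme_minimal()
}

#' Cells in principal-component space
#'
#' @param object A [pca_cells()] embedding.
#' @param labels Optional named vector or tibble mapping cells to a label
#'   (e.g. cell line) used for colour.
#' @param ... Unused.
#' @return A ggplot of the first two components (or PC1 against 0 if k = 1).
#' @export
autoplot.cell_embedding <- function(object, labels = NULL, ...) {
  df <- tibble::as_tibble(object)
  expl <- attr(object, "explained")
  if (!"PC2" %in% names(df)) df$PC2 <- 0
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      lab_col <- setdiff(names(labels), "cell")[1L]
      labels <- stats::setNames(labels[[lab_col]], labels$cell)
    }
    df$label <- labels[df$cell]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * expl[1L]),
      y = if (length(expl) > 1) sprintf("PC2 (%.1f%%)", 100 * expl[2L]) else "") +
    ggplot2::theme_minimal()
  if (is.null(labels)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label))
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
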