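#' Heatmap of a parameter correlation matrix
#'
#' @param report a `correlation_report` from [correlation_matrix()].
#' @param significant optional logical matrix (same shape as `report$r`)
#'   marking cross-subject-significant pairs with an asterisk.
#' @return a ggplot object.
#' @export
plot_correlation_heatmap <- function(report, significant = NULL) {
  stopifnot(inherits(report, "correlation_report"))
  r <- report$r
  df <- expand.grid(x = colnames(r), y = rownames(r),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$r <- as.vector(t(r))
  df$lab <- ""
  if (!is.null(significant))
    df$lab[!is.na(df$r) & as.vector(t(significant))] <- "*"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), size = 5) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = if (is.null(report$organ)) "Parameter correlations"
                          else paste0(report$organ, " parameter correlations"),
                  subtitle = sprintf("%d near-optimal fits",
                                     report$n_points)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Two-dimensional density view of a parameter pair
#'
#' Filled-contour rendering of [kde2d_pair()] with the near-optimal fit
#' locations overlaid; ridge-shaped crests indicate a practically
#' non-identifiable pair.
#'
#' @param kd result of [kde2d_pair()].
#' @return a ggplot object.
#' @export
plot_kde2d_pair <- function(kd) {
  grid <- expand.grid(x = kd$x, y = kd$y, KEEP.OUT.ATTRS = FALSE)
  grid$z <- as.vector(kd$z)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$z), colour = "white",
                          alpha = 0.5, bins = 8) +
    ggplot2::geom_point(data = kd$points, size = 0.4, alpha = 0.5,
                        colour = "black") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = kd$px, y = kd$py, fill = "density") +
    ggplot2::theme_minimal()
}
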