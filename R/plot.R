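# Basic ggplot2 renderers: spatial scatter, palette swatches, CVD preview,
# and adjacency heatmaps.

#' Scatter plot of spatial cells, optionally with assigned colors
#'
#' @param cells A [spatial_cells()] table.
#' @param coloring Optional `cluster_coloring`; cluster colors fall back to
#'   ggplot2 defaults when absent.
#' @param point_size Point size.
#' @return A ggplot object.
#' @export
plot_cells <- function(cells, coloring = NULL, point_size = 0.8) {
  cells <- check_cells(cells)
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y,
                                           colour = .data$cluster)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(coloring)) {
    lut <- setNames(coloring$mapping$hex, coloring$mapping$cluster)
    p <- p + ggplot2::scale_colour_manual(values = lut)
  }
  p
}

#' Swatch plot of a palette
#'
#' @param palette A `cw_palette` or hex vector.
#' @return A ggplot object.
#' @export
plot_palette <- function(palette) {
  palette <- as_palette(palette)
  df <- mutate(palette, idx = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = 1, fill = .data$hex)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_text(ggplot2::aes(label = .data$hex), angle = 90, size = 2.6) +
    ggplot2::theme_void()
}

#' Preview a palette under dichromatic vision
#'
#' One swatch row per view: the original palette and its three simulated
#' deficiency renderings.
#'
#' @param palette A `cw_palette` or hex vector.
#' @return A ggplot object.
#' @export
plot_cvd_preview <- function(palette) {
  palette <- as_palette(palette)
  views <- c("original", "protanopia", "deuteranopia", "tritanopia")
  df <- bind_rows(lapply(views, function(v) {
    hex <- if (v == "original") palette$hex else simulate_cvd(palette$hex, v)
    tibble(view = v, idx = seq_along(hex), hex = hex)
  }))
  df$view <- factor(df$view, levels = rev(views))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$view,
                                   fill = .data$hex)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

heat_plot <- function(adj, value_name) {
  df <- as_tibble(as.data.frame.table(adj, responseName = "w",
                                      stringsAsFactors = FALSE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Var1, y = .data$Var2,
                                   fill = .data$w)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value_name) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a cluster interlacement graph
#' @param object A `ci_graph`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ci_graph <- function(object, ...) heat_plot(object$adjacency, "DOI")

#' Heatmap of a color-difference graph
#' @param object A `cd_graph`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cd_graph <- function(object, ...) {
  heat_plot(object$adjacency, "ΔC")
}

#' Spatial rendering of a colorized dataset
#' @param object A `cluster_coloring`.
#' @param cells The [spatial_cells()] the coloring was computed on.
#' @param ... Passed to [plot_cells()].
#' @return A ggplot object.
#' @export
autoplot.cluster_coloring <- function(object, cells, ...) {
  plot_cells(cells, coloring = object, ...)
}
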