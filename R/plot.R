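#' Colorwash of one dose-grid slice
#'
#' A ggplot2 raster of a grid slice with optional isodose contour overlays,
#' in world coordinates.
#'
#' @param grid a [voxel_grid()] (dose, H/D or density).
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param index slice index along the plane's axis (default: middle slice).
#' @param contour_levels optional numeric levels to overlay as contours.
#' @return A ggplot object.
#' @export
plot_dose_slice <- function(grid, plane = "sagittal", index = NULL,
                            contour_levels = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  ax <- plane_axes(plane)
  if (is.null(index))
    index <- ceiling(grid$dims[ax$slice_axis] / 2)
  m <- slice_matrix(grid, plane, index)
  coords <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$dims[a]) - 0.5) * grid$spacing[a])
  df <- tidyr::expand_grid(v = coords[[ax$in_plane[2]]],
                           u = coords[[ax$in_plane[1]]])
  df$value <- as.vector(m)  # column-major: u fastest
  df <- df[, c("u", "v", "value")]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = grid$value_kind) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (cm)", y = "v (cm)",
                  title = sprintf("%s slice %d", plane, index)) +
    ggplot2::theme_minimal()
  if (!is.null(contour_levels))
    p <- p + ggplot2::geom_contour(
      ggplot2::aes(z = .data$value), breaks = contour_levels,
      colour = "white", linewidth = 0.3, inherit.aes = TRUE)
  p
}

#' Plot cumulative dose-volume histograms
#'
#' @param x a DVH tibble from [dvh()] (may hold several structures).
#' @param ... ignored.
#' @return A ggplot object.
#' @export
plot_dvh <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(.data$dose_pct,
                                  100 * .data$volume_fraction,
                                  colour = .data$structure,
                                  group = .data$structure)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "dose (% of prescription)", y = "volume (%)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_dvh
#' @param object a DVH tibble from [dvh()].
#' @export
autoplot.straydose_dvh <- function(object, ...) plot_dvh(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
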