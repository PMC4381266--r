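#' @useDynLib straydose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

grid_density_values <- function(grid, table) {
  g <- as_density_grid(grid, table)
  as.numeric(g$values)
}

#' Exact voxel traversal of a line segment
#'
#' Parametric (Siddon-style) traversal: every voxel crossed by the segment
#' `p0 -> p1`, with the geometric chord length inside each. Chords of zero
#' length at exact face/edge hits are dropped; voxel assignment is decided at
#' the chord midpoint, so boundary rays are handled deterministically.
#'
#' @param grid a [voxel_grid()].
#' @param p0,p1 world endpoints (cm), length-3.
#' @return A tibble with 1-based voxel indices `i, j, k` and `length` (cm),
#'   plus attributes `in_grid_length` and `total_length`.
#' @export
siddon_chords <- function(grid, p0, p1) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (all(p0 == p1)) stop("degenerate segment: p0 == p1", call. = FALSE)
  res <- cpp_siddon_chords(as.numeric(p0), as.numeric(p1),
                           grid$origin, grid$spacing,
                           as.integer(grid$dims))
  out <- tibble::tibble(
    i = res$ijk[, 1] + 1L, j = res$ijk[, 2] + 1L, k = res$ijk[, 3] + 1L,
    length = res$length
  )
  attr(out, "in_grid_length") <- res$in_grid_length
  attr(out, "total_length") <- res$total_length
  out
}

#' Radiological (water-equivalent) pathlength between two points
#'
#' Sums chord length times relative density over every voxel the segment
#' traverses; portions of the segment outside the grid contribute with
#' `outside_density` (air by default, mirroring a source upstream of the
#' patient). Symmetric in its endpoints.
#'
#' @param grid anatomy [voxel_grid()] (HU or density).
#' @param p0,p1 world endpoints (cm).
#' @param table [hu_table()] used when the grid holds HU.
#' @param outside_density relative density outside the raster (default 0.001).
#' @return Water-equivalent pathlength in cm.
#' @export
radiological_pathlength <- function(grid, p0, p1, table = default_hu_table(),
                                    outside_density = 0.001) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (all(p0 == p1)) stop("degenerate segment: p0 == p1", call. = FALSE)
  wepl_batch(grid, as.numeric(p0), matrix(as.numeric(p1), nrow = 1),
             table = table, outside_density = outside_density)[1]
}

# batch WEPL from one source to many points; pts is n x 3
wepl_batch <- function(grid, src, pts, table = default_hu_table(),
                       outside_density = 0.001) {
  dens <- grid_density_values(grid, table)
  cpp_wepl_batch(as.numeric(src), pts, grid$origin, grid$spacing,
                 as.integer(grid$dims), dens, outside_density)
}

#' Orthonormal beam frame for a given axis
#'
#' A fixed right-handed frame `(u, v, axis)`: `u` and `v` span the plane
#' perpendicular to the beam. The in-plane orientation is deterministic so
#' apertures and beam's-eye-view projections are reproducible.
#'
#' @param axis beam direction, any nonzero length-3 vector (normalised here).
#' @return List with unit vectors `u`, `v`, `axis`.
#' @export
beam_frame_basis <- function(axis) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("beam axis must be nonzero", call. = FALSE)
  axis <- axis / n
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- c(ref[2] * axis[3] - ref[3] * axis[2],
         ref[3] * axis[1] - ref[1] * axis[3],
         ref[1] * axis[2] - ref[2] * axis[1])
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = v, axis = axis)
}

#' Express world points in beam coordinates
#'
#' Converts one or more world points to the beam frame of a virtual source:
#' lateral offsets `x, y`, axial distance `z` along the beam axis, geometric
#' source distance `d`, and (when an anatomy grid is supplied) the
#' water-equivalent pathlength `dprime` from the source to the point.
#'
#' @param points world point (length 3) or `n x 3` matrix.
#' @param source world position of the virtual source (cm).
#' @param axis beam direction (normalised internally).
#' @param grid optional anatomy [voxel_grid()] for `dprime`; when `NULL`,
#'   `dprime` is `NA`.
#' @param table [hu_table()] for HU grids.
#' @param outside_density relative density outside the raster.
#' @return A tibble with columns `x, y, z, d, dprime` (cm), one row per point.
#' @export
to_beam_frame <- function(points, source, axis, grid = NULL,
                          table = default_hu_table(),
                          outside_density = 0.001) {
  if (is.null(dim(points))) points <- matrix(as.numeric(points), nrow = 1)
  basis <- beam_frame_basis(axis)
  rel <- sweep(points, 2, as.numeric(source))
  d <- sqrt(rowSums(rel^2))
  if (any(d == 0))
    stop("point coincides with the source", call. = FALSE)
  out <- tibble::tibble(
    x = as.numeric(rel %*% basis$u),
    y = as.numeric(rel %*% basis$v),
    z = as.numeric(rel %*% basis$axis),
    d = d,
    dprime = NA_real_
  )
  if (!is.null(grid))
    out$dprime <- wepl_batch(grid, source, points, table, outside_density)
  out
}
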