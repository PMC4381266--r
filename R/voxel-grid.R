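#' Regular voxel grid with world-coordinate geometry
#'
#' The basic spatial container: a 3-D axis-aligned raster of scalar values
#' (Hounsfield units, relative water-equivalent density, or dose) with the
#' world position of its corner and isotropic or anisotropic voxel spacing in
#' centimetres. Voxel `(i, j, k)` (1-based in R) occupies the half-open box
#' `[origin + (i-1)*spacing, origin + i*spacing)` per axis.
#'
#' @param values numeric 3-D array of voxel values.
#' @param spacing voxel edge lengths in cm, length 1 (isotropic) or 3.
#' @param origin world coordinates (cm) of the corner of voxel `(1,1,1)`.
#' @param value_kind what the values are: `"HU"`, `"density"` (relative
#'   water-equivalent density), `"Gy"`, `"Sv"`, `"mSv/Gy"` or `"percent"`.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0),
                       value_kind = c("density", "HU", "Gy", "Sv",
                                      "mSv/Gy", "percent")) {
  value_kind <- match.arg(value_kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite on all axes", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("voxel values must all be finite", call. = FALSE)
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), dims = dim(values),
         value_kind = value_kind),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels [%s]\n",
              x$dims[1], x$dims[2], x$dims[3], x$value_kind))
  cat(sprintf("  spacing: %s cm; origin: (%s) cm\n",
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) x$dims

#' World coordinates of all voxel centers
#'
#' @param grid a [voxel_grid()].
#' @return An `n x 3` matrix of voxel-center coordinates (cm) in the grid's
#'   column-major storage order (first axis fastest).
#' @export
voxel_centers <- function(grid) {
  cx <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * grid$spacing[3]
  cbind(
    rep(cx, times = grid$dims[2] * grid$dims[3]),
    rep(rep(cy, each = grid$dims[1]), times = grid$dims[3]),
    rep(cz, each = grid$dims[1] * grid$dims[2])
  )
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_differs <- function(a, b, what = "grids") {
  if (!same_geometry(a, b))
    stop(sprintf("%s have mismatched geometry (dims/spacing/origin)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Structure mask aligned to a voxel grid
#'
#' A named boolean per-voxel mask (target, organ, body outline) sharing the
#' geometry of its anatomy grid.
#'
#' @param mask logical 3-D array, same dimensions as `grid`.
#' @param grid the [voxel_grid()] the mask is aligned to.
#' @param name structure name.
#' @return A `structure_mask` object.
#' @export
structure_mask <- function(mask, grid, name = "structure") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.array(mask) || !is.logical(mask) ||
      !all(dim(mask) == grid$dims))
    stop("`mask` must be a logical array matching the grid dimensions",
         call. = FALSE)
  structure(
    list(mask = mask, dims = grid$dims, spacing = grid$spacing,
         origin = grid$origin, name = name),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d of %d voxels\n",
              x$name, sum(x$mask), prod(x$dims)))
  invisible(x)
}

#' Hounsfield-unit to relative density lookup table
#'
#' Piecewise-linear conversion from CT numbers to relative water-equivalent
#' density, clamped at both ends. Water (0 HU -> 1.0) must be on the curve.
#' The packaged default is a generic 4-point stand-in for a clinic-calibrated
#' CT calibration curve.
#'
#' @param hu numeric vector of HU breakpoints, strictly increasing.
#' @param density relative densities at the breakpoints, all `>= 0`.
#' @return An `hu_table` (tibble of breakpoints with class attributes).
#' @export
hu_table <- function(hu, density) {
  stopifnot(length(hu) == length(density), length(hu) >= 2L)
  if (any(diff(hu) <= 0))
    stop("HU breakpoints must be strictly increasing", call. = FALSE)
  if (any(density < 0))
    stop("densities must be non-negative", call. = FALSE)
  if (!any(hu == 0 & abs(density - 1) < 1e-12)) {
    # water must map to 1.0 exactly; interpolated water is accepted too
    if (min(hu) <= 0 && max(hu) >= 0) {
      at0 <- stats::approx(hu, density, xout = 0)$y
      if (abs(at0 - 1) > 1e-9)
        stop("the table must map 0 HU (water) to density 1.0", call. = FALSE)
    } else {
      stop("the table must cover 0 HU (water) with density 1.0", call. = FALSE)
    }
  }
  structure(tibble::tibble(hu = as.numeric(hu), density = as.numeric(density)),
            class = c("hu_table", "tbl_df", "tbl", "data.frame"))
}

#' @rdname hu_table
#' @export
default_hu_table <- function() {
  hu_table(hu = c(-1000, 0, 100, 1500),
           density = c(0.001, 1.0, 1.05, 1.6))
}

#' Convert Hounsfield units to relative water-equivalent density
#'
#' @param hu numeric vector of HU values (all finite).
#' @param table an [hu_table()]; clamped outside its breakpoint range.
#' @return Numeric vector of relative densities.
#' @export
hu_to_density <- function(hu, table = default_hu_table()) {
  stopifnot(inherits(table, "hu_table"))
  if (anyNA(hu) || any(!is.finite(hu)))
    stop("HU values must be finite", call. = FALSE)
  stats::approx(table$hu, table$density, xout = hu, rule = 2)$y
}

#' Convert an HU grid to a relative-density grid
#'
#' Grids already holding densities pass through unchanged.
#'
#' @param grid a [voxel_grid()] with `value_kind` `"HU"` or `"density"`.
#' @param table an [hu_table()].
#' @return A `voxel_grid` with `value_kind = "density"`.
#' @export
as_density_grid <- function(grid, table = default_hu_table()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grid$value_kind == "density") return(grid)
  if (grid$value_kind != "HU")
    stop("only HU grids can be converted to density", call. = FALSE)
  vals <- array(hu_to_density(as.vector(grid$values), table), dim = grid$dims)
  voxel_grid(vals, grid$spacing, grid$origin, value_kind = "density")
}

#' Read a two-column HU calibration CSV
#'
#' @param path CSV file with columns `hu` and `density`.
#' @return An [hu_table()].
#' @export
read_hu_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("hu", "density") %in% names(df)))
    stop("HU table CSV needs columns `hu` and `density`", call. = FALSE)
  hu_table(df$hu, df$density)
}
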