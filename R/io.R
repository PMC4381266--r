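#' Read and write voxel grids as NIfTI volumes
#'
#' Grid geometry travels in the NIfTI sform: a diagonal affine holding the
#' voxel spacing, with the translation at the center of the first voxel
#' (NIfTI convention). Values are written as float64, so density and dose
#' rasters round-trip bit-exactly.
#'
#' @param grid a [voxel_grid()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @param sidecar optional list written alongside as a JSON sidecar
#'   (`<path>.json`) recording provenance: model parameters, source
#'   geometry, prescription, units.
#' @return `write_volume()`: invisibly, `path`.
#' @export
write_volume <- function(grid, path, sidecar = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$values)
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin + grid$spacing / 2
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar)) {
    sidecar$units <- sidecar$units %||% grid$value_kind
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param value_kind what the stored values are (see [voxel_grid()]).
#' @return `read_volume()`: a [voxel_grid()].
#' @export
read_volume <- function(path, value_kind = "density") {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- diag(aff)[1:3]
  origin <- aff[1:3, 4] - spacing / 2
  voxel_grid(array(as.numeric(img), dim = dim(img)), spacing, origin,
             value_kind = value_kind)
}

#' @rdname write_volume
#' @param mask a [structure_mask()]; stored as an integer label volume.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  g <- grid_from_mask(mask)
  g$values <- array(as.numeric(mask$mask), dim = mask$dims)
  write_volume(g, path)
}

#' @rdname write_volume
#' @param grid_ref a [voxel_grid()] or [structure_mask()] whose geometry the
#'   mask must match (checked), or `NULL` to accept the file's own geometry.
#' @param name structure name for the returned mask.
#' @export
read_mask <- function(path, grid_ref = NULL, name = "structure") {
  g <- read_volume(path, value_kind = "density")
  if (!is.null(grid_ref)) stop_if_geometry_differs(g, grid_ref, "mask/grid")
  structure_mask(array(g$values > 0.5, dim = g$dims), g, name = name)
}
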