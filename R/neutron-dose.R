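#' Neutron H/D at calculation points
#'
#' Evaluates the four-component analytical model at points expressed in beam
#' coordinates: a power-law divergence term in the source distance `d`,
#' per-component exponential attenuation in the water-equivalent pathlength
#' difference `dprime - dprime_iso`, and per-component lateral Gaussians
#' whose width scales linearly with the axial distance `z` (widths are
#' defined at the isocenter plane). See [neutron_model()] for the formula.
#'
#' Points at or behind the source plane are rejected: the lateral term
#' diverges as `z -> 0` and the model only describes the forward half-space.
#'
#' @param model a [neutron_model()].
#' @param pt data frame with columns `x, y, z, d, dprime` (cm), e.g. from
#'   [to_beam_frame()]; vectorised over rows.
#' @param z_min minimum axial distance beyond the source plane (cm).
#' @return Numeric vector of H/D values in mSv per Gy.
#' @export
hd_at_point <- function(model, pt, z_min = 0.1) {
  stopifnot(inherits(model, "neutron_model"))
  pt <- tibble::as_tibble(pt)
  need <- c("x", "y", "z", "d", "dprime")
  if (!all(need %in% names(pt)))
    stop("pt needs columns x, y, z, d, dprime", call. = FALSE)
  if (any(pt$z <= z_min))
    stop(sprintf("point(s) at or behind the source plane (z <= %g cm)", z_min),
         call. = FALSE)
  if (any(pt$d == 0)) stop("d = 0: point coincides with source", call. = FALSE)
  hd_eval(model, pt$x, pt$y, pt$z, pt$d, pt$dprime)
}

# vectorised core of the four-component model; no input checks
hd_eval <- function(model, x, y, z, d, dprime) {
  comp <- model$components
  r2 <- x^2 + y^2
  acc <- 0
  for (i in seq_len(nrow(comp))) {
    ex <- -comp$alpha[i] * (dprime - model$dprime_iso) -
      r2 * model$d_iso^2 / (2 * comp$sigma[i]^2 * z^2)
    acc <- acc + comp$C[i] * exp(pmin(ex, 700))
  }
  model$field_size_factor * model$hd_iso * (d / model$d_iso)^(-model$p) * acc
}

#' Neutron H/D over a whole voxel grid
#'
#' Evaluates the analytical model at every voxel center of the anatomy grid:
#' each voxel is ray-traced from the virtual neutron source to obtain its
#' water-equivalent pathlength, converted to beam coordinates, and scored.
#' Unless overridden, `dprime_iso` is recomputed per call by tracing the
#' source-to-isocenter ray through the same anatomy, keeping the attenuation
#' reference consistent with the volume being scored.
#'
#' Voxels at or behind the source plane (axial distance `<= z_min`) receive
#' zero with a count recorded in attribute `"n_behind_source"`.
#'
#' @param model a [neutron_model()].
#' @param anatomy [voxel_grid()] of HU or relative density.
#' @param source world position (cm) of the virtual neutron source (the
#'   downstream face of the patient collimator, on the central axis).
#' @param axis beam direction.
#' @param isocenter world isocenter (cm); needed when `dprime_iso` is
#'   recomputed.
#' @param table [hu_table()] for HU anatomies.
#' @param z_min forward half-space cutoff, cm (default 0.1).
#' @param outside_density relative density outside the raster.
#' @param recompute_dprime_iso recompute `dprime_iso` from the anatomy
#'   (default `TRUE`); set `FALSE` to use the model's configured value, e.g.
#'   for water-tank reproductions.
#' @return A [voxel_grid()] of H/D in mSv/Gy with the anatomy's geometry.
#' @export
hd_grid <- function(model, anatomy, source, axis, isocenter = NULL,
                    table = default_hu_table(), z_min = 0.1,
                    outside_density = 0.001, recompute_dprime_iso = TRUE) {
  stopifnot(inherits(model, "neutron_model"), inherits(anatomy, "voxel_grid"))
  if (recompute_dprime_iso) {
    if (is.null(isocenter))
      stop("isocenter is required to recompute dprime_iso", call. = FALSE)
    model$dprime_iso <- radiological_pathlength(
      anatomy, source, isocenter, table = table,
      outside_density = outside_density)
  }
  centers <- voxel_centers(anatomy)
  bf <- to_beam_frame(centers, source, axis, grid = anatomy, table = table,
                      outside_density = outside_density)
  ok <- bf$z > z_min
  vals <- numeric(nrow(bf))
  if (any(ok))
    vals[ok] <- hd_eval(model, bf$x[ok], bf$y[ok], bf$z[ok], bf$d[ok],
                        bf$dprime[ok])
  out <- voxel_grid(array(vals, dim = anatomy$dims), anatomy$spacing,
                    anatomy$origin, value_kind = "mSv/Gy")
  attr(out, "n_behind_source") <- sum(!ok)
  attr(out, "dprime_iso") <- model$dprime_iso
  if (sum(!ok) > 0)
    message(sum(!ok), " voxel(s) at or behind the source plane set to 0")
  out
}

#' Neutron equivalent dose from an H/D grid and a prescription
#'
#' @param hdgrid [voxel_grid()] of H/D in mSv/Gy.
#' @param prescription prescribed proton dose at isocenter, Gy; `>= 0`.
#' @return A [voxel_grid()] of neutron equivalent dose in Sv.
#' @export
neutron_equivalent_dose <- function(hdgrid, prescription) {
  stopifnot(inherits(hdgrid, "voxel_grid"))
  if (hdgrid$value_kind != "mSv/Gy")
    stop("hdgrid must hold H/D values in mSv/Gy", call. = FALSE)
  if (!is.finite(prescription) || prescription < 0)
    stop("prescription must be a non-negative dose in Gy", call. = FALSE)
  voxel_grid(hdgrid$values * prescription / 1000, hdgrid$spacing,
             hdgrid$origin, value_kind = "Sv")
}
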