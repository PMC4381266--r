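#' Passive-scattering beam plan
#'
#' Geometry and delivery parameters for a single passively scattered proton
#' field: a virtual point source, beam axis, the collimator (aperture) plane
#' at `collimator_z` cm downstream of the source, and the prescription
#' defined at the isocenter. The virtual neutron source of the leakage model
#' sits at the center of the collimator plane.
#'
#' @param source world position (cm) of the virtual proton source.
#' @param axis beam direction (normalised internally).
#' @param collimator_z distance (cm) from source to the collimator plane;
#'   `> 0` and upstream of the isocenter.
#' @param isocenter world isocenter (cm).
#' @param prescription prescribed dose at isocenter, Gy; `> 0`.
#' @param energy nominal proton energy entering the nozzle, MeV (metadata
#'   for the surrogate engine).
#' @param modulation range-modulation width in cm water-equivalent, or
#'   `"auto"` to derive it from the target via [modulation_width()].
#' @param range_shifter range-shifter thickness, cm water-equivalent
#'   (bookkeeping; the surrogate sets per-ray range from the target's distal
#'   edge, so the shifter is implicit).
#' @return A `beam_plan` object.
#' @export
beam_plan <- function(source, axis, collimator_z, isocenter, prescription,
                      energy = NA_real_, modulation = "auto",
                      range_shifter = 0) {
  basis <- beam_frame_basis(axis)
  z_iso <- sum((as.numeric(isocenter) - as.numeric(source)) * basis$axis)
  if (!is.finite(collimator_z) || collimator_z <= 0)
    stop("collimator_z must be > 0", call. = FALSE)
  if (z_iso <= collimator_z)
    stop("isocenter must lie downstream of the collimator plane",
         call. = FALSE)
  if (!is.finite(prescription) || prescription <= 0)
    stop("prescription must be > 0 Gy", call. = FALSE)
  if (!identical(modulation, "auto") &&
      (!is.numeric(modulation) || modulation < 0))
    stop("modulation must be \"auto\" or a width >= 0 (cm WED)",
         call. = FALSE)
  structure(
    list(source = as.numeric(source), axis = basis$axis, basis = basis,
         collimator_z = collimator_z, isocenter = as.numeric(isocenter),
         z_iso = z_iso, prescription = prescription, energy = energy,
         modulation = modulation, range_shifter = range_shifter),
    class = "beam_plan"
  )
}

#' @export
print.beam_plan <- function(x, ...) {
  cat(sprintf("<beam_plan> %s MeV, prescription %.3g Gy\n",
              ifelse(is.na(x$energy), "?", format(x$energy)), x$prescription))
  cat(sprintf("  source (%s) cm, axis (%s)\n",
              paste(signif(x$source, 4), collapse = ", "),
              paste(signif(x$axis, 3), collapse = ", ")))
  cat(sprintf("  collimator at %.4g cm, isocenter at %.4g cm (axial)\n",
              x$collimator_z, x$z_iso))
  cat(sprintf("  modulation: %s; range shifter: %.3g cm WED\n",
              if (identical(x$modulation, "auto")) "auto"
              else sprintf("%.3g cm WED", x$modulation), x$range_shifter))
  invisible(x)
}

#' Shape parameters of the surrogate proton dose engine
#'
#' @param entrance_plateau depth-dose value at zero depth relative to the
#'   spread-out-Bragg-peak plateau (default 0.75); rises linearly to 1 at
#'   the start of the modulated region.
#' @param distal_falloff distance (cm water-equivalent) over which the dose
#'   falls from the plateau to near zero beyond the distal edge
#'   (default 0.6; below 1e-5 of the plateau within 1 cm).
#' @param sigma_pen lateral penumbra sigma at isocenter scale, cm
#'   (default 0.5); grows linearly with distance from the source.
#' @param penumbra_margin offset (cm, at isocenter scale) of the 50% penumbra
#'   level outside the geometric field edge (default 0.8) — the analytical
#'   analogue of the aperture margin used clinically so the target stays
#'   covered while the dose still falls below 1e-5 of the central value
#'   3 cm outside the field edge.
#' @param lateral_cutoff hard zero beyond this distance (cm, collimator
#'   scale) outside the aperture (default 3).
#' @return List of engine parameters.
#' @export
sobp_params <- function(entrance_plateau = 0.75, distal_falloff = 0.6,
                        sigma_pen = 0.5, penumbra_margin = 0.8,
                        lateral_cutoff = 3) {
  stopifnot(entrance_plateau >= 0, entrance_plateau <= 1,
            distal_falloff > 0, sigma_pen > 0, penumbra_margin >= 0,
            lateral_cutoff > 0)
  list(entrance_plateau = entrance_plateau, distal_falloff = distal_falloff,
       sigma_pen = sigma_pen, penumbra_margin = penumbra_margin,
       lateral_cutoff = lateral_cutoff)
}

erfc_ <- function(x) 2 * stats::pnorm(-x * sqrt(2))

#' Closed-form spread-out-Bragg-peak depth dose
#'
#' Normalised depth-dose of the surrogate engine along one ray: a linear
#' entrance ramp from `entrance_plateau` at zero depth to 1 at the start of
#' the modulated region, a flat plateau of width `modulation` ending at
#' `range`, and a smooth error-function distal falloff (continuous at the
#' distal edge, below 1e-5 within 1 cm).
#'
#' @param depth water-equivalent depth(s) from the source, cm.
#' @param range per-ray distal range, cm water-equivalent.
#' @param modulation modulation width, cm water-equivalent.
#' @param params [sobp_params()].
#' @return Depth-dose factor(s) in `[0, 1]`.
#' @export
sobp_depth_dose <- function(depth, range, modulation,
                            params = sobp_params()) {
  w <- params$distal_falloff
  s <- w / 5
  sobp_start <- pmax(range - modulation, 0)
  out <- numeric(length(depth))
  ramp <- depth < sobp_start
  if (any(ramp)) {
    frac <- depth[ramp] / sobp_start[if (length(sobp_start) > 1) ramp else 1]
    out[ramp] <- params$entrance_plateau + (1 - params$entrance_plateau) * frac
  }
  rng <- if (length(range) > 1) range else rep(range, length(depth))
  ss <- if (length(sobp_start) > 1) sobp_start else rep(sobp_start, length(depth))
  flat <- depth >= ss & depth <= rng
  out[flat] <- 1
  distal <- depth > rng
  if (any(distal)) {
    delta <- depth[distal] - rng[distal]
    f0 <- 0.5 * erfc_((-w / 2) / (s * sqrt(2)))
    out[distal] <- 0.5 * erfc_((delta - w / 2) / (s * sqrt(2))) / f0
  }
  out[!is.finite(out)] <- 0
  pmin(pmax(out, 0), 1)
}

# aperture raster on the collimator plane: open mask + pixel-center (u, v)
new_aperture <- function(open, u, v, spacing, plan) {
  structure(list(open = open, u = u, v = v, spacing = spacing,
                 collimator_z = plan$collimator_z, basis = plan$basis,
                 source = plan$source),
            class = "aperture")
}

#' @export
print.aperture <- function(x, ...) {
  cat(sprintf(
    "<aperture> %d x %d pixels (%.3g cm), %d open (%.3g cm^2) at z = %.4g cm\n",
    length(x$u), length(x$v), x$spacing, sum(x$open),
    sum(x$open) * x$spacing^2, x$collimator_z))
  invisible(x)
}

# world positions of collimator-plane points given (u, v) coordinates
aperture_world <- function(ap, u, v) {
  n <- length(u)
  matrix(ap$source, n, 3, byrow = TRUE) +
    outer(rep(ap$collimator_z, n), ap$basis$axis) +
    outer(u, ap$basis$u) + outer(v, ap$basis$v)
}

# beam-frame (x, y, z) of many world points, geometry only
beam_xyz <- function(points, plan) {
  rel <- sweep(points, 2, plan$source)
  list(x = as.numeric(rel %*% plan$basis$u),
       y = as.numeric(rel %*% plan$basis$v),
       z = as.numeric(rel %*% plan$basis$axis))
}

#' Project a target to beam's eye view to form the aperture
#'
#' A collimator-plane pixel is open iff the divergent ray from the source
#' through that pixel's center intersects at least one target voxel (no
#' margin): the open region is the beam's-eye-view silhouette of the target
#' scaled to the collimator plane.
#'
#' @param ptv target [structure_mask()].
#' @param anatomy anatomy [voxel_grid()] sharing the mask geometry.
#' @param plan a [beam_plan()].
#' @param pixel_spacing collimator-plane pixel size, cm (default 0.2).
#' @param pad extra raster margin around the projected target, cm
#'   (default 1.5).
#' @return An `aperture` object.
#' @export
project_aperture <- function(ptv, anatomy, plan, pixel_spacing = 0.2,
                             pad = 1.5) {
  stopifnot(inherits(ptv, "structure_mask"), inherits(plan, "beam_plan"))
  stop_if_geometry_differs(ptv, anatomy, "ptv/anatomy")
  if (!any(ptv$mask)) stop("PTV mask is empty", call. = FALSE)
  centers <- voxel_centers(anatomy)[as.vector(ptv$mask), , drop = FALSE]
  b <- beam_xyz(centers, plan)
  if (any(b$z <= 0))
    stop("PTV voxels at or behind the source", call. = FALSE)
  sc <- plan$collimator_z / b$z
  pu <- b$x * sc
  pv <- b$y * sc
  u <- seq(min(pu) - pad, max(pu) + pad, by = pixel_spacing)
  v <- seq(min(pv) - pad, max(pv) + pad, by = pixel_spacing)
  pix <- cbind(rep(u, times = length(v)), rep(v, each = length(u)))
  world <- aperture_world(
    structure(list(source = plan$source, basis = plan$basis,
                   collimator_z = plan$collimator_z), class = "aperture"),
    pix[, 1], pix[, 2])
  dens <- grid_density_values(anatomy, default_hu_table())
  hits <- cpp_ray_mask_depths(plan$source, world, anatomy$origin,
                              anatomy$spacing, as.integer(anatomy$dims),
                              dens, as.vector(ptv$mask), 0.001)
  open <- matrix(hits[, 1] > 0, nrow = length(u), ncol = length(v))
  new_aperture(open, u, v, pixel_spacing, plan)
}

# per-pixel ray depths of a mask (proximal/distal WEPL from the source)
aperture_ray_depths <- function(ap, mask, anatomy, table = default_hu_table(),
                                outside_density = 0.001) {
  pix <- cbind(rep(ap$u, times = length(ap$v)),
               rep(ap$v, each = length(ap$u)))
  world <- aperture_world(ap, pix[, 1], pix[, 2])
  dens <- grid_density_values(anatomy, table)
  cpp_ray_mask_depths(ap$source, world, anatomy$origin, anatomy$spacing,
                      as.integer(anatomy$dims), dens, as.vector(mask$mask),
                      outside_density)
}

#' Range-modulation width of a target
#'
#' Width of the spread-out Bragg peak needed to cover the target: over all
#' beam's-eye-view rays that intersect it, the maximal difference between
#' the radiological depths of the target's distal and proximal edges. The
#' default `"global"` reading takes `max(distal) - min(proximal)` over rays
#' (the conservative envelope); `"per_ray"` takes the largest single-ray
#' thickness.
#'
#' @param ptv target [structure_mask()].
#' @param anatomy anatomy [voxel_grid()].
#' @param plan a [beam_plan()].
#' @param reading `"global"` (default) or `"per_ray"`.
#' @param table [hu_table()] for HU anatomies.
#' @param pixel_spacing ray raster spacing on the collimator plane, cm.
#' @return Modulation width in cm water-equivalent.
#' @export
modulation_width <- function(ptv, anatomy, plan, reading = c("global",
                                                             "per_ray"),
                             table = default_hu_table(),
                             pixel_spacing = 0.2) {
  reading <- match.arg(reading)
  ap <- project_aperture(ptv, anatomy, plan, pixel_spacing = pixel_spacing)
  depths <- aperture_ray_depths(ap, ptv, anatomy, table)
  hit <- depths[, 1] > 0
  if (!any(hit)) stop("no BEV ray intersects the PTV", call. = FALSE)
  if (reading == "global")
    max(depths[hit, 3]) - min(depths[hit, 2])
  else
    max(depths[hit, 3] - depths[hit, 2])
}

#' Passive-scattering surrogate target (PTV_PS)
#'
#' Expands the target so a scanned-beam-style engine mimics passive
#' scattering: a voxel belongs to PTV_PS iff its beam's-eye-view ray falls
#' in the open aperture and its radiological depth lies within the
#' modulation band ending at the distal target edge of its ray,
#' `[distal - modulation, distal]`. The target itself is always contained
#' in homogeneous media.
#'
#' @param ptv target [structure_mask()].
#' @param anatomy anatomy [voxel_grid()].
#' @param plan a [beam_plan()]; `plan$modulation` may be `"auto"`.
#' @param aperture optional precomputed [project_aperture()] result.
#' @param modulation optional precomputed width, cm water-equivalent.
#' @param table [hu_table()] for HU anatomies.
#' @return A [structure_mask()] named `"PTV_PS"` with attributes
#'   `"aperture"` and `"modulation"`.
#' @export
build_ptv_ps <- function(ptv, anatomy, plan, aperture = NULL,
                         modulation = NULL, table = default_hu_table()) {
  stopifnot(inherits(ptv, "structure_mask"), inherits(plan, "beam_plan"))
  stop_if_geometry_differs(ptv, anatomy, "ptv/anatomy")
  if (is.null(aperture))
    aperture <- project_aperture(ptv, anatomy, plan)
  if (is.null(modulation)) {
    modulation <- if (identical(plan$modulation, "auto"))
      modulation_width(ptv, anatomy, plan, table = table)
    else plan$modulation
  }
  centers <- voxel_centers(anatomy)
  b <- beam_xyz(centers, plan)
  depth <- wepl_batch(anatomy, plan$source, centers, table)

  # each voxel's own BEV ray against the target: inside-silhouette flag and
  # the distal target depth along that ray
  dens <- grid_density_values(anatomy, table)
  own <- cpp_ray_mask_depths(plan$source, centers, anatomy$origin,
                             anatomy$spacing, as.integer(anatomy$dims),
                             dens, as.vector(ptv$mask), 0.001)
  hit <- own[, 1] > 0
  distal <- own[, 3]

  # rays that miss the target but fall in an open pixel take that pixel's ray
  open_idx <- aperture_pixel_index(aperture, b)
  pix_depths <- aperture_ray_depths(aperture, ptv, anatomy, table)
  pix_ok <- !is.na(open_idx) & as.vector(aperture$open)[pmax(open_idx, 1L)] &
    !hit
  pix_ok[pix_ok] <- pix_depths[open_idx[pix_ok], 1] > 0
  distal[pix_ok] <- pix_depths[open_idx[pix_ok], 3]

  # half-thickness of each voxel along the beam (WEPL), so the band
  # [distal - modulation, distal] is met by any voxel whose chord overlaps
  # it: with zero modulation this selects the distal-edge shell rather than
  # an empty set, without pushing the distal edge deeper
  ax_dom <- which.max(abs(plan$axis))
  half_wepl <- 0.5 * anatomy$spacing[ax_dom] * dens
  in_field <- (hit | pix_ok) & b$z > 0
  member <- in_field & depth <= distal + 1e-4 &
    depth >= distal - modulation - half_wepl - 1e-4
  out <- structure_mask(array(member, dim = anatomy$dims),
                        grid_from_mask(ptv), name = "PTV_PS")
  attr(out, "aperture") <- aperture
  attr(out, "modulation") <- modulation
  out
}

# dummy voxel_grid carrying a mask's geometry (for structure_mask())
grid_from_mask <- function(m) {
  structure(list(values = array(0, m$dims), spacing = m$spacing,
                 origin = m$origin, dims = m$dims, value_kind = "density"),
            class = "voxel_grid")
}

# linear index of the aperture pixel containing each beam-frame point
# (projected to the collimator plane); NA when outside the raster or z <= 0
aperture_pixel_index <- function(ap, b) {
  nu <- length(ap$u); nv <- length(ap$v)
  sc <- ap$collimator_z / b$z
  pu <- b$x * sc
  pv <- b$y * sc
  iu <- round((pu - ap$u[1]) / ap$spacing) + 1
  iv <- round((pv - ap$v[1]) / ap$spacing) + 1
  ok <- b$z > 0 & iu >= 1 & iu <= nu & iv >= 1 & iv <= nv
  idx <- rep(NA_integer_, length(pu))
  idx[ok] <- as.integer(iu[ok] + nu * (iv[ok] - 1))
  idx
}

# signed distance (cm, collimator scale) from projected points to the open
# aperture edge: negative inside the field, positive outside
aperture_signed_distance <- function(ap, b, inside) {
  nu <- length(ap$u); nv <- length(ap$v)
  open <- ap$open
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, nu, nv)
    si <- seq_len(nu) + di; sj <- seq_len(nv) + dj
    ok_i <- si >= 1 & si <= nu; ok_j <- sj >= 1 & sj <= nv
    out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
    out
  }
  closed_nbr <- !shift(open, 1, 0) | !shift(open, -1, 0) |
    !shift(open, 0, 1) | !shift(open, 0, -1)
  boundary <- open & closed_nbr
  if (!any(boundary)) boundary <- open  # tiny fields: every pixel is edge
  bidx <- which(boundary)
  refs <- cbind(ap$u[(bidx - 1) %% nu + 1], ap$v[(bidx - 1) %/% nu + 1])
  sc <- ap$collimator_z / b$z
  pts <- cbind(b$x * sc, b$y * sc)
  pts[b$z <= 0, ] <- 1e6  # behind source: effectively infinitely far outside
  md <- cpp_min_dist2(pts, refs)
  dist <- md$dist
  ifelse(inside, -dist, dist)
}

#' Surrogate passive-scattering proton dose grid
#'
#' Deterministic closed-form stand-in for a pencil-beam treatment-planning
#' dose engine: per voxel, dose is `prescription x SOBP(depth) x P(lateral)`,
#' where the spread-out Bragg peak ([sobp_depth_dose()]) uses each ray's
#' distal PTV_PS radiological depth as its range (guaranteeing conformal
#' distal coverage) and `P` is an error-function lateral penumbra around the
#' aperture edge, diverging with distance from the source. Dose at the
#' isocenter equals the prescription to within 0.5%.
#'
#' @param plan a [beam_plan()].
#' @param anatomy anatomy [voxel_grid()].
#' @param ptv_ps the surrogate target from [build_ptv_ps()] (with its
#'   aperture and modulation attributes), or any target mask plus explicit
#'   `aperture`/`modulation` arguments.
#' @param aperture,modulation overrides for the attributes carried by
#'   `ptv_ps`.
#' @param table [hu_table()] for HU anatomies.
#' @param params engine shape parameters, see [sobp_params()].
#' @return A [voxel_grid()] of proton absorbed dose in Gy.
#' @export
proton_dose_grid <- function(plan, anatomy, ptv_ps, aperture = NULL,
                             modulation = NULL, table = default_hu_table(),
                             params = sobp_params()) {
  stopifnot(inherits(plan, "beam_plan"), inherits(ptv_ps, "structure_mask"))
  stop_if_geometry_differs(ptv_ps, anatomy, "ptv_ps/anatomy")
  aperture <- aperture %||% attr(ptv_ps, "aperture")
  modulation <- modulation %||% attr(ptv_ps, "modulation")
  if (is.null(aperture) || is.null(modulation))
    stop("ptv_ps must carry aperture/modulation (see build_ptv_ps) or they ",
         "must be supplied", call. = FALSE)
  if (!any(ptv_ps$mask)) stop("PTV_PS is empty", call. = FALSE)
  if (!any(aperture$open)) stop("aperture has no open pixels", call. = FALSE)
  iso <- plan$isocenter
  inside_grid <- all(iso >= anatomy$origin) &&
    all(iso < anatomy$origin + anatomy$spacing * anatomy$dims)
  if (!inside_grid) stop("isocenter lies outside the grid", call. = FALSE)

  centers <- voxel_centers(anatomy)
  b <- beam_xyz(centers, plan)
  depth <- wepl_batch(anatomy, plan$source, centers, table)
  dens <- grid_density_values(anatomy, table)

  # per-ray distal range from the voxel's own ray through PTV_PS; rays that
  # miss it borrow the range of the nearest open-edge pixel's ray
  own <- cpp_ray_mask_depths(plan$source, centers, anatomy$origin,
                             anatomy$spacing, as.integer(anatomy$dims),
                             dens, as.vector(ptv_ps$mask), 0.001)
  hit <- own[, 1] > 0
  rng <- own[, 3]

  open_idx <- aperture_pixel_index(aperture, b)
  inside <- hit |
    (!is.na(open_idx) & as.vector(aperture$open)[pmax(open_idx, 1L)])
  sdist <- aperture_signed_distance(aperture, b, inside)

  if (any(!hit)) {
    pix_depths <- aperture_ray_depths(aperture, ptv_ps, anatomy, table)
    # out-of-field voxels borrow the range of the nearest open pixel's ray
    nb <- nearest_open_pixel(aperture, b, !hit)
    rng_miss <- pix_depths[nb, 3]
    bad <- is.na(rng_miss) | pix_depths[nb, 1] == 0
    rng_miss[bad] <- plan$z_iso  # fallback: nominal range at the isocenter
    rng[!hit] <- rng_miss
  }

  sobp <- sobp_depth_dose(depth, rng, modulation, params)

  # penumbra at isocenter scale; divergence cancels between the offset and
  # the sigma, both growing linearly with z
  t_iso <- sdist * plan$z_iso / aperture$collimator_z
  pen <- 0.5 * erfc_((t_iso - params$penumbra_margin) /
                       (params$sigma_pen * sqrt(2)))
  pen[sdist >= params$lateral_cutoff] <- 0
  pen[b$z <= 0] <- 0

  dose <- plan$prescription * sobp * pen
  dose[dose < plan$prescription * 1e-12] <- 0
  out <- voxel_grid(array(dose, dim = anatomy$dims), anatomy$spacing,
                    anatomy$origin, value_kind = "Gy")
  attr(out, "modulation") <- modulation
  out
}

# index (into the aperture raster, linear) of the open pixel nearest to each
# selected voxel's projected position
nearest_open_pixel <- function(ap, b, sel) {
  nu <- length(ap$u)
  oidx <- which(as.vector(ap$open))
  refs <- cbind(ap$u[(oidx - 1) %% nu + 1], ap$v[(oidx - 1) %/% nu + 1])
  sc <- ap$collimator_z / b$z
  pts <- cbind((b$x * sc)[sel], (b$y * sc)[sel])
  pts[!is.finite(pts)] <- 1e6
  md <- cpp_min_dist2(pts, refs)
  oidx[md$which]
}
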