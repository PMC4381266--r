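#' Water-box phantom with a spherical target
#'
#' The standard commissioning-style geometry: a 30 x 15 x 15 cm^3 box of
#' water (relative density 1) containing a 5-cm-diameter spherical target
#' centered on the beam axis at 7.5 cm depth. The beam travels along +x;
#' the world origin is the target center (= isocenter), so the entrance
#' face sits at x = -7.5 cm. Everything outside the box is air (handled by
#' the tracer's outside density).
#'
#' @param spacing isotropic voxel size in cm (default 0.25); must divide the
#'   box edge lengths and be smaller than the target radius.
#' @param box_cm box edge lengths (beam, lateral, lateral), cm.
#' @param target_diameter_cm sphere diameter, cm.
#' @param depth_cm depth of the sphere center below the entrance face, cm.
#' @return List with `anatomy` (a density [voxel_grid()]), `target` (a
#'   [structure_mask()]) and `isocenter` (world cm).
#' @export
make_water_box <- function(spacing = 0.25, box_cm = c(30, 15, 15),
                           target_diameter_cm = 5, depth_cm = 7.5) {
  r <- target_diameter_cm / 2
  if (spacing > r)
    stop("spacing must not exceed the target radius", call. = FALSE)
  dims <- box_cm / spacing
  if (any(abs(dims - round(dims)) > 1e-9))
    stop("spacing must divide the box dimensions", call. = FALSE)
  dims <- as.integer(round(dims))
  origin <- c(-depth_cm, -box_cm[2] / 2, -box_cm[3] / 2)
  grid <- voxel_grid(array(1, dim = dims), spacing, origin,
                     value_kind = "density")
  cen <- voxel_centers(grid)
  inside <- rowSums(cen^2) <= r^2
  target <- structure_mask(array(inside, dim = dims), grid, name = "target")
  list(anatomy = grid, target = target, isocenter = c(0, 0, 0))
}

#' Default single-field plan for the water-box phantom
#'
#' A single field along +x: virtual proton source 230 cm upstream of the
#' isocenter, collimator plane 33 cm upstream of the isocenter (so the
#' virtual neutron source-to-isocenter distance is 33 cm), 140 MeV, with
#' the modulation width derived from the target.
#'
#' @param prescription prescribed dose at isocenter, Gy (default 36).
#' @param sad source-to-isocenter distance, cm.
#' @param collimator_to_iso collimator-to-isocenter distance, cm.
#' @param isocenter world isocenter.
#' @param energy nominal energy, MeV.
#' @return A [beam_plan()].
#' @export
water_box_plan <- function(prescription = 36, sad = 230,
                           collimator_to_iso = 33,
                           isocenter = c(0, 0, 0), energy = 140) {
  beam_plan(source = isocenter - c(sad, 0, 0), axis = c(1, 0, 0),
            collimator_z = sad - collimator_to_iso, isocenter = isocenter,
            prescription = prescription, energy = energy,
            modulation = "auto")
}

#' Thorax-like heterogeneous phantom
#'
#' A geometric stand-in for a mediastinal-irradiation patient: an
#' elliptical-cylinder soft-tissue body with an anterior surface bulge, two
#' low-density lung ellipsoids, a bone-density spinal column, a spherical
#' mediastinal target between the lungs, a neck extension, and a small
#' thyroid more than 15 cm superior of the target center so the far-field
#' dose regime is reachable. Axes: x anterior->posterior (beam direction),
#' y left-right, z inferior->superior; the world origin is the target
#' center.
#'
#' Densities are generic tissue values (soft tissue 1.0, lung 0.26, bone
#' 1.4, air 0.001 outside the body); optional Gaussian density noise inside
#' the body emulates CT texture.
#'
#' @param spacing isotropic voxel size in cm (default 0.5).
#' @param noise_sd standard deviation of optional density noise (default 0,
#'   off).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return List with `anatomy` (density [voxel_grid()]), `masks` (list of
#'   [structure_mask()]: `target`, `lungs`, `thyroid`, `body`) and
#'   `isocenter`.
#' @export
make_thorax <- function(spacing = 0.5, noise_sd = 0, seed = 1L) {
  ext_lo <- c(-12, -16, -12)
  ext_hi <- c(12, 16, 24)
  dims <- as.integer(round((ext_hi - ext_lo) / spacing))
  grid0 <- voxel_grid(array(0.001, dim = dims), spacing, ext_lo,
                      value_kind = "density")
  cen <- voxel_centers(grid0)
  x <- cen[, 1]; y <- cen[, 2]; z <- cen[, 3]

  in_ell <- function(c0, semi)
    ((x - c0[1]) / semi[1])^2 + ((y - c0[2]) / semi[2])^2 +
    ((z - c0[3]) / semi[3])^2 <= 1

  torso <- (x / 10)^2 + (y / 15)^2 <= 1 & z >= -12 & z < 14
  neck <- (x / 5)^2 + (y / 5)^2 <= 1 & z >= 14 & z <= 24
  bulge <- in_ell(c(-8, 6, 2), c(3.5, 4, 5)) |
    in_ell(c(-8, -6, 2), c(3.5, 4, 5))
  body <- torso | neck | bulge

  lungs <- in_ell(c(1, 8, 4), c(6, 5.5, 9)) |
    in_ell(c(1, -8, 4), c(6, 5.5, 9))
  lungs <- lungs & body
  spine <- (x - 7)^2 + y^2 <= 1.5^2 & z >= -12 & z <= 20 & body
  target <- x^2 + y^2 + z^2 <= 2.5^2
  thyroid <- in_ell(c(-2, 0, 18.5), c(1, 2, 1.5)) & body

  dens <- rep(0.001, length(x))
  dens[body] <- 1.0
  dens[lungs] <- 0.26
  dens[spine] <- 1.4
  dens[target] <- 1.0
  if (noise_sd > 0) {
    set.seed(seed)
    dens[body] <- pmax(dens[body] + stats::rnorm(sum(body), 0, noise_sd),
                       0.01)
  }
  anatomy <- voxel_grid(array(dens, dim = dims), spacing, ext_lo,
                        value_kind = "density")
  msk <- function(v, name)
    structure_mask(array(v, dim = dims), anatomy, name = name)
  list(anatomy = anatomy,
       masks = list(target = msk(target, "target"),
                    lungs = msk(lungs, "lungs"),
                    thyroid = msk(thyroid, "thyroid"),
                    body = msk(body, "body")),
       isocenter = c(0, 0, 0))
}

#' Default single anterior field for the thorax phantom
#'
#' @inheritParams water_box_plan
#' @param energy nominal energy, MeV (default 160).
#' @return A [beam_plan()].
#' @export
thorax_plan <- function(prescription = 36, sad = 230, collimator_to_iso = 33,
                        isocenter = c(0, 0, 0), energy = 160) {
  beam_plan(source = isocenter - c(sad, 0, 0), axis = c(1, 0, 0),
            collimator_z = sad - collimator_to_iso, isocenter = isocenter,
            prescription = prescription, energy = energy,
            modulation = "auto", range_shifter = 1.5)
}

#' Write a phantom (volume + structure labels + manifest) to disk
#'
#' The density raster is written as NIfTI (float64, bit-exact round trip),
#' the structure masks as one integer label volume per structure, and a
#' JSON manifest records geometry and structure names.
#'
#' @param phantom result of [make_water_box()] or [make_thorax()].
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return Invisibly, the named vector of files written.
#' @export
write_fixture <- function(phantom, dir, name = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(anatomy = file.path(dir, paste0(name, "_density.nii.gz")))
  write_volume(phantom$anatomy, files[["anatomy"]])
  masks <- phantom$masks %||% list(target = phantom$target)
  for (nm in names(masks)) {
    f <- file.path(dir, paste0(name, "_mask_", nm, ".nii.gz"))
    write_mask(masks[[nm]], f)
    files[[paste0("mask_", nm)]] <- f
  }
  manifest <- list(
    name = name,
    dims = phantom$anatomy$dims, spacing = phantom$anatomy$spacing,
    origin = phantom$anatomy$origin,
    isocenter = phantom$isocenter,
    structures = names(masks)
  )
  mf <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files[["manifest"]] <- mf
  invisible(files)
}
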