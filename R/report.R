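#' Combine proton and neutron equivalent-dose grids
#'
#' Voxelwise sum: proton absorbed dose enters with a radiation weighting
#' factor of 1 (1 Gy -> 1 Sv), neutron equivalent dose is already in Sv.
#' Commutative and associative; preserves non-negativity.
#'
#' @param proton [voxel_grid()] of proton dose in Gy (or Sv).
#' @param neutron [voxel_grid()] of neutron equivalent dose in Sv.
#' @return A [voxel_grid()] of combined equivalent dose in Sv.
#' @export
combine_equivalent_dose <- function(proton, neutron) {
  stopifnot(inherits(proton, "voxel_grid"), inherits(neutron, "voxel_grid"))
  stop_if_geometry_differs(proton, neutron, "proton/neutron grids")
  if (!proton$value_kind %in% c("Gy", "Sv"))
    stop("proton grid must be in Gy or Sv", call. = FALSE)
  if (neutron$value_kind != "Sv")
    stop("neutron grid must be in Sv", call. = FALSE)
  voxel_grid(proton$values + neutron$values, proton$spacing, proton$origin,
             value_kind = "Sv")
}

#' Structure dose statistics
#'
#' Mean, spread and extrema of equivalent dose over a structure's voxels,
#' with the mean also expressed as a percentage of the prescription. The
#' quoted spread is the population standard deviation over voxels (divide
#' by n); set `sd = "sample"` for the n-1 convention.
#'
#' @param dose [voxel_grid()] in Sv (or Gy, weighted 1:1 to Sv).
#' @param mask non-empty [structure_mask()] aligned to the dose grid.
#' @param prescription prescribed dose at isocenter, Gy (= Sv at weighting
#'   factor 1).
#' @param sd `"population"` (default) or `"sample"`.
#' @return A one-row tibble: `structure`, `n_voxels`, `mean_Sv`, `sd_Sv`,
#'   `min_Sv`, `max_Sv`, `pct_of_prescription`.
#' @export
structure_stats <- function(dose, mask, prescription,
                            sd = c("population", "sample")) {
  sd <- match.arg(sd)
  stopifnot(inherits(dose, "voxel_grid"), inherits(mask, "structure_mask"))
  stop_if_geometry_differs(dose, mask, "dose/mask")
  if (!any(mask$mask)) stop("structure mask is empty", call. = FALSE)
  if (!is.finite(prescription) || prescription <= 0)
    stop("prescription must be > 0", call. = FALSE)
  v <- dose$values[mask$mask]
  n <- length(v)
  s <- if (n > 1) stats::sd(v) * if (sd == "population")
    sqrt((n - 1) / n) else 1 else 0
  tibble::tibble(
    structure = mask$name, n_voxels = n,
    mean_Sv = mean(v), sd_Sv = s, min_Sv = min(v), max_Sv = max(v),
    pct_of_prescription = 100 * mean(v) / prescription
  )
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each dose level,
#' binned at `bin_pct` of the prescription (1% resolution by default).
#' Starts at 100% volume for zero dose and is non-increasing.
#'
#' @inheritParams structure_stats
#' @param bin_pct dose-bin width as percent of prescription.
#' @return A tibble: `structure`, `dose_pct`, `dose_Sv`, `volume_fraction`.
#' @export
dvh <- function(dose, mask, prescription, bin_pct = 1) {
  stopifnot(inherits(dose, "voxel_grid"), inherits(mask, "structure_mask"))
  stop_if_geometry_differs(dose, mask, "dose/mask")
  if (!any(mask$mask)) stop("structure mask is empty", call. = FALSE)
  v <- 100 * dose$values[mask$mask] / prescription
  top <- max(bin_pct, ceiling(max(v) / bin_pct) * bin_pct)
  levels <- seq(0, top, by = bin_pct)
  out <- tibble::tibble(
    structure = mask$name,
    dose_pct = levels,
    dose_Sv = levels * prescription / 100,
    volume_fraction = vapply(levels, function(l) mean(v >= l), numeric(1))
  )
  class(out) <- c("straydose_dvh", class(out))
  out
}

#' Rescale a dose grid to percent of prescription
#'
#' @param dose [voxel_grid()] in Gy or Sv.
#' @param prescription prescribed dose at isocenter (> 0).
#' @return A [voxel_grid()] with `value_kind = "percent"`.
#' @export
percent_of_prescription <- function(dose, prescription) {
  stopifnot(inherits(dose, "voxel_grid"))
  if (!is.finite(prescription) || prescription <= 0)
    stop("prescription must be > 0", call. = FALSE)
  voxel_grid(100 * dose$values / prescription, dose$spacing, dose$origin,
             value_kind = "percent")
}

plane_axes <- function(plane) {
  switch(plane,
         axial = list(slice_axis = 3L, in_plane = c(1L, 2L)),
         sagittal = list(slice_axis = 2L, in_plane = c(1L, 3L)),
         coronal = list(slice_axis = 1L, in_plane = c(2L, 3L)),
         stop("plane must be axial, sagittal or coronal", call. = FALSE))
}

slice_matrix <- function(grid, plane, index) {
  ax <- plane_axes(plane)$slice_axis
  switch(as.character(ax),
         "1" = grid$values[index, , ],
         "2" = grid$values[, index, ],
         "3" = grid$values[, , index])
}

#' Isodose contours on grid slices
#'
#' Marching-squares style contours (via [grDevices::contourLines()]) of a
#' percent-dose grid at the requested levels, slice by slice. Levels outside
#' the slice's data range simply produce no contour.
#'
#' @param dose_pct [voxel_grid()] with `value_kind = "percent"` (see
#'   [percent_of_prescription()]).
#' @param levels isodose levels (percent), ascending.
#' @param plane `"axial"` (constant 3rd axis), `"sagittal"` (constant 2nd)
#'   or `"coronal"` (constant 1st).
#' @param slices slice indices along that axis (default: all).
#' @return A tibble of polylines: `plane`, `slice`, `position_cm`, `level`,
#'   `contour_id`, `u`, `v` (world cm of the two in-plane axes).
#' @export
isodose_bands <- function(dose_pct, levels, plane = "sagittal",
                          slices = NULL) {
  stopifnot(inherits(dose_pct, "voxel_grid"))
  if (is.unsorted(levels)) stop("levels must be ascending", call. = FALSE)
  ax <- plane_axes(plane)
  if (is.null(slices)) slices <- seq_len(dose_pct$dims[ax$slice_axis])
  coords <- lapply(1:3, function(a)
    dose_pct$origin[a] + (seq_len(dose_pct$dims[a]) - 0.5) *
      dose_pct$spacing[a])
  u_ax <- ax$in_plane[1]; v_ax <- ax$in_plane[2]
  rows <- list()
  for (s in slices) {
    m <- slice_matrix(dose_pct, plane, s)
    if (max(m) == min(m)) next  # constant slice: no interior contour
    cl <- grDevices::contourLines(coords[[u_ax]], coords[[v_ax]], m,
                                  levels = levels)
    for (ci in seq_along(cl)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        plane = plane, slice = s,
        position_cm = coords[[ax$slice_axis]][s],
        level = cl[[ci]]$level, contour_id = ci,
        u = cl[[ci]]$x, v = cl[[ci]]$y
      )
    }
  }
  if (!length(rows))
    return(tibble::tibble(plane = character(), slice = integer(),
                          position_cm = numeric(), level = numeric(),
                          contour_id = integer(), u = numeric(),
                          v = numeric()))
  dplyr::bind_rows(rows)
}

#' Run the full phantom-to-report pipeline
#'
#' Generates a phantom, builds the passive-scattering surrogate target and
#' proton dose, evaluates the neutron H/D model over the anatomy, combines
#' the equivalent doses, and writes dose rasters (NIfTI + JSON sidecars),
#' per-structure statistics and DVHs (CSV), and a JSON run manifest with
#' parameters and per-stage wall times.
#'
#' For the thorax phantom a field-size correction is applied: the blocked
#' fraction of a circular total field of `total_field_diameter` cm on the
#' collimator plane multiplies `hd_iso` (collimator-neutron yield scales
#' with the blocked area; the model calibration assumes a closed
#' collimator).
#'
#' @param output_dir directory for all artifacts.
#' @param phantom `"water_box"` or `"thorax"`.
#' @param model a [neutron_model()] (default: the packaged illustrative
#'   set).
#' @param prescription prescribed dose, Gy.
#' @param spacing phantom voxel size, cm (default 0.25 for the water box,
#'   0.5 for the thorax).
#' @param total_field_diameter diameter (cm) of the total proton field on
#'   the collimator used for the field-size correction (thorax only;
#'   `NULL` skips the correction).
#' @param seed RNG seed recorded in the manifest and used for any optional
#'   phantom noise.
#' @param noise_sd density noise passed to [make_thorax()].
#' @return Invisibly, a list with the grids, masks, statistics tibble and
#'   manifest.
#' @export
run_pipeline <- function(output_dir, phantom = c("water_box", "thorax"),
                         model = default_neutron_model(),
                         prescription = 36, spacing = NULL,
                         total_field_diameter = 10, seed = 1L,
                         noise_sd = 0) {
  phantom <- match.arg(phantom)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    el <- proc.time()[["elapsed"]] - t0
    logf("stage %-14s %.2f s", name, el)
    timings[[name]] <<- el
    res
  }
  timings <- list()
  logf("straydose pipeline: phantom=%s prescription=%g Gy seed=%d",
       phantom, prescription, seed)

  ph <- stage("phantom", {
    if (phantom == "water_box")
      make_water_box(spacing = spacing %||% 0.25)
    else
      make_thorax(spacing = spacing %||% 0.5, noise_sd = noise_sd,
                  seed = seed)
  })
  anatomy <- ph$anatomy
  target <- if (phantom == "water_box") ph$target else ph$masks$target
  plan <- if (phantom == "water_box")
    water_box_plan(prescription = prescription, isocenter = ph$isocenter)
  else thorax_plan(prescription = prescription, isocenter = ph$isocenter)

  ptv_ps <- stage("ptv_ps", build_ptv_ps(target, anatomy, plan))
  aperture <- attr(ptv_ps, "aperture")

  proton <- stage("proton_dose",
                  proton_dose_grid(plan, anatomy, ptv_ps))

  if (phantom == "thorax" && !is.null(total_field_diameter)) {
    fsf <- stage("field_size", {
      pu <- rep(aperture$u, times = length(aperture$v))
      pv <- rep(aperture$v, each = length(aperture$u))
      total <- matrix(pu^2 + pv^2 <= (total_field_diameter / 2)^2,
                      nrow = length(aperture$u))
      field_size_correction(aperture$open & total, total)
    })
    model$field_size_factor <- fsf
    logf("field-size correction factor: %.4f", fsf)
  }

  neutron_source <- plan$source + plan$collimator_z * plan$axis
  hd <- stage("neutron_hd",
              hd_grid(model, anatomy, source = neutron_source,
                      axis = plan$axis, isocenter = plan$isocenter))
  neutron <- stage("neutron_dose",
                   neutron_equivalent_dose(hd, prescription))
  combined <- stage("combine", combine_equivalent_dose(proton, neutron))

  masks <- if (phantom == "water_box") list(target = target) else ph$masks
  stats <- stage("report", {
    dplyr::bind_rows(lapply(names(masks), function(nm) {
      dplyr::bind_rows(
        dplyr::mutate(structure_stats(combined, masks[[nm]], prescription),
                      dose = "combined", .before = 1),
        dplyr::mutate(structure_stats(neutron, masks[[nm]], prescription),
                      dose = "neutron", .before = 1)
      )
    }))
  })

  stage("write", {
    sidecar <- list(
      model = list(hd_iso = model$hd_iso, p = model$p,
                   d_iso = model$d_iso, dprime_iso = attr(hd, "dprime_iso"),
                   field_size_factor = model$field_size_factor,
                   components = model$components),
      source = neutron_source, axis = plan$axis,
      prescription_Gy = prescription, seed = seed
    )
    write_volume(proton, file.path(output_dir, "proton_dose_Gy.nii.gz"),
                 sidecar = sidecar)
    write_volume(neutron, file.path(output_dir, "neutron_dose_Sv.nii.gz"),
                 sidecar = sidecar)
    write_volume(combined, file.path(output_dir, "combined_dose_Sv.nii.gz"),
                 sidecar = sidecar)
    utils::write.csv(stats, file.path(output_dir, "structure_stats.csv"),
                     row.names = FALSE)
    dvhs <- dplyr::bind_rows(lapply(masks, function(m)
      dvh(combined, m, prescription)))
    utils::write.csv(dvhs, file.path(output_dir, "dvh.csv"),
                     row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("straydose")),
      phantom = phantom, prescription_Gy = prescription, seed = seed,
      modulation_cm = attr(ptv_ps, "modulation"),
      field_size_factor = model$field_size_factor,
      dprime_iso_cm = attr(hd, "dprime_iso"),
      stage_seconds = timings
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(anatomy = anatomy, masks = masks, plan = plan,
                 ptv_ps = ptv_ps, proton = proton, hd = hd,
                 neutron = neutron, combined = combined, stats = stats,
                 timings = timings))
}
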