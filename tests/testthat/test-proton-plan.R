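test_that("aperture projection follows similar triangles", {
  wb <- make_water_box()
  # source 233 cm from isocenter, collimator plane at 200 cm from source
  plan <- water_box_plan(sad = 233)
  ap <- project_aperture(wb$target, wb$anatomy, plan, pixel_spacing = 0.1)
  open_diam <- 2 * sqrt(sum(ap$open) * ap$spacing^2 / pi)
  # 5 cm sphere projected: 5 * 200 / 233 = 4.29 cm, plus up to a voxel of
  # silhouette inflation from boundary voxel boxes
  expect_equal(open_diam, 5 * 200 / 233, tolerance = 0.05)

  # single-voxel target opens roughly that voxel's projected footprint
  mk <- array(FALSE, dim = wb$anatomy$dims)
  mk[30, 30, 30] <- TRUE
  one <- structure_mask(mk, wb$anatomy, "one")
  ap1 <- project_aperture(one, wb$anatomy, plan, pixel_spacing = 0.02)
  a1 <- sum(ap1$open) * ap1$spacing^2
  expect_equal(a1, (0.25 * 200 / 233)^2, tolerance = 0.15)

  # parallel-beam limit: silhouette at natural scale
  planP <- beam_plan(source = c(-1e5, 0, 0), axis = c(1, 0, 0),
                     collimator_z = 1e5 - 33, isocenter = c(0, 0, 0),
                     prescription = 36)
  apP <- project_aperture(wb$target, wb$anatomy, planP, pixel_spacing = 0.1)
  expect_equal(2 * sqrt(sum(apP$open) * apP$spacing^2 / pi), 5,
               tolerance = 0.05)

  empty <- structure_mask(array(FALSE, dim = wb$anatomy$dims),
                          wb$anatomy, "none")
  expect_error(project_aperture(empty, wb$anatomy, plan), "empty")
})

test_that("modulation width is the radiological extent of the target", {
  sc <- coarse_water_scene()
  mw <- modulation_width(sc$wb$target, sc$wb$anatomy, sc$plan)
  expect_equal(mw, 5, tolerance = 0.15)   # 5 cm sphere in water

  # half-density medium halves the radiological extent
  half <- voxel_grid(sc$wb$anatomy$values * 0.5, sc$wb$anatomy$spacing,
                     sc$wb$anatomy$origin)
  mw2 <- modulation_width(sc$wb$target, half, sc$plan)
  expect_equal(mw2, 2.5, tolerance = 0.1)

  # per-ray reading never exceeds the global envelope
  mwr <- modulation_width(sc$wb$target, sc$wb$anatomy, sc$plan,
                          reading = "per_ray")
  expect_lte(mwr, mw + 1e-9)
  expect_equal(mwr, 5, tolerance = 0.15)

  # single-voxel target on a 0.2 cm grid: its own thickness
  g <- voxel_grid(array(1, dim = c(50, 20, 20)), 0.2, c(-5, -2, -2))
  mk <- array(FALSE, dim = c(50, 20, 20)); mk[25, 10, 10] <- TRUE
  one <- structure_mask(mk, g, "one")
  pl <- beam_plan(source = c(-235, 0, 0), axis = c(1, 0, 0),
                  collimator_z = 200, isocenter = c(-0.1, -0.1, -0.1),
                  prescription = 36)
  expect_equal(modulation_width(one, g, pl, pixel_spacing = 0.05), 0.2,
               tolerance = 0.01)
})

test_that("PTV_PS contains the target and degenerates sensibly", {
  sc <- coarse_water_scene()
  pps <- build_ptv_ps(sc$wb$target, sc$wb$anatomy, sc$plan)
  expect_true(all(pps$mask[sc$wb$target$mask]))
  expect_gt(sum(pps$mask), sum(sc$wb$target$mask))
  expect_equal(attr(pps, "modulation"), 5, tolerance = 0.3)

  # zero modulation: a thin distal-edge shell, nothing beyond the distal
  # target depth and nothing deeper than one voxel upstream of it
  shell <- build_ptv_ps(sc$wb$target, sc$wb$anatomy, sc$plan,
                        modulation = 0)
  expect_gt(sum(shell$mask), 0)
  expect_lt(sum(shell$mask), sum(sc$wb$target$mask) / 2)
  # shell voxels lie on the distal half of the target's silhouette
  cen <- voxel_centers(sc$wb$anatomy)
  expect_true(all(cen[as.vector(shell$mask), 1] > 0))

  # single-voxel target collapses to (essentially) that voxel
  g <- voxel_grid(array(1, dim = c(50, 20, 20)), 0.2, c(-5, -2, -2))
  mk <- array(FALSE, dim = c(50, 20, 20)); mk[25, 10, 10] <- TRUE
  one <- structure_mask(mk, g, "one")
  pl <- beam_plan(source = c(-235, 0, 0), axis = c(1, 0, 0),
                  collimator_z = 200, isocenter = c(-0.1, -0.1, -0.1),
                  prescription = 36)
  ap <- project_aperture(one, g, pl, pixel_spacing = 0.05)
  mw <- modulation_width(one, g, pl, pixel_spacing = 0.05)
  pps1 <- build_ptv_ps(one, g, pl, aperture = ap, modulation = mw)
  expect_true(pps1$mask[25, 10, 10])
  expect_lte(sum(pps1$mask), 3)
})

test_that("surrogate dose engine covers the target and falls off as specified", {
  sc <- coarse_water_scene()
  pps <- build_ptv_ps(sc$wb$target, sc$wb$anatomy, sc$plan)
  dose <- proton_dose_grid(sc$plan, sc$wb$anatomy, pps)
  presc <- sc$plan$prescription

  tv <- dose$values[sc$wb$target$mask]
  expect_gt(mean(tv) / presc, 0.99)
  expect_lt(mean(tv) / presc, 1.01)

  # isocenter voxel at full prescription
  iidx <- round((c(0, 0, 0) - dose$origin) / dose$spacing + 0.5)
  expect_equal(dose$values[iidx[1], iidx[2], iidx[3]], presc,
               tolerance = 0.005)

  # bounded and clean
  expect_true(all(dose$values >= 0))
  expect_true(all(dose$values <= 1.05 * presc))

  # zero far outside the field (>= 4 cm lateral of the field edge)
  cen <- voxel_centers(dose)
  r <- sqrt(cen[, 2]^2 + cen[, 3]^2)
  far <- abs(cen[, 1]) < 0.3 & r > 6.6
  expect_true(all(dose$values[far] == 0))

  expect_error(proton_dose_grid(sc$plan, sc$wb$anatomy, sc$wb$target),
               "aperture")
})

test_that("per-ray depth dose matches an independent SOBP closed form", {
  sc <- coarse_water_scene()
  pps <- build_ptv_ps(sc$wb$target, sc$wb$anatomy, sc$plan)
  dose <- proton_dose_grid(sc$plan, sc$wb$anatomy, pps)
  mod <- attr(pps, "modulation")
  presc <- sc$plan$prescription
  anat <- sc$wb$anatomy
  cen <- voxel_centers(anat)
  dens <- rep(1, prod(anat$dims))

  # 50 random rays through the open field: compare the whole depth profile
  set.seed(77)
  lat <- cbind(runif(50, -1.5, 1.5), runif(50, -1.5, 1.5))
  for (i in 1:50) {
    col <- which(abs(cen[, 2] - lat[i, 1]) < anat$spacing[2] / 2 &
                   abs(cen[, 3] - lat[i, 2]) < anat$spacing[3] / 2)
    col <- col[order(cen[col, 1])]
    depth <- straydose:::wepl_batch(anat, sc$plan$source,
                                    cen[col, , drop = FALSE])
    ray <- straydose:::cpp_ray_mask_depths(
      sc$plan$source, cen[col[1], , drop = FALSE], anat$origin,
      anat$spacing, as.integer(anat$dims), dens, as.vector(pps$mask),
      0.001)
    expected <- presc * sobp_oracle(depth, ray[1, 3], mod)
    got <- dose$values[col]
    # penumbra is ~1 deep inside the field; compare where it cannot bite
    keep <- depth < ray[1, 3] + 2
    expect_equal(got[keep], expected[keep], tolerance = 0.02)
  }
})

test_that("plan validation catches inconsistent geometry", {
  expect_error(beam_plan(c(0, 0, 0), c(1, 0, 0), collimator_z = 50,
                         isocenter = c(40, 0, 0), prescription = 36),
               "downstream")
  expect_error(beam_plan(c(0, 0, 0), c(1, 0, 0), collimator_z = 50,
                         isocenter = c(60, 0, 0), prescription = 0),
               "prescription")
  expect_error(beam_plan(c(0, 0, 0), c(0, 0, 0), collimator_z = 50,
                         isocenter = c(60, 0, 0), prescription = 1),
               "nonzero")
})
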