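test_that("the point model reproduces closed-form special cases", {
  # exactly-binary weights sum to 1 exactly, so the isocenter point returns
  # hd_iso exactly
  m <- toy_model(components = toy_components(C = c(0.5, 0.25, 0.125, 0.125)))
  iso <- tibble::tibble(x = 0, y = 0, z = 33, d = 33, dprime = 7.5)
  expect_identical(hd_at_point(m, iso), m$hd_iso)

  # pure inverse power law on axis with matched dprime
  m1 <- toy_model(p = 1,
                  components = toy_components(C = c(0.5, 0.25, 0.125, 0.125)))
  far <- tibble::tibble(x = 0, y = 0, z = 66, d = 66, dprime = 7.5)
  expect_equal(hd_at_point(m1, far), m1$hd_iso / 2, tolerance = 1e-12)

  # frozen hand evaluation: single active component, off-axis, attenuated
  # 3.68 * (sqrt(1114)/33)^-1 * exp(-0.5) * exp(-25/200) = 1.9475338
  mh <- suppressWarnings(neutron_model(
    3.68, 1, 33, 10,
    toy_components(C = c(1, 0, 0, 0), alpha = c(0.1, 0, 0, 0),
                   sigma = c(10, 1, 1, 1))))
  pt <- tibble::tibble(x = 5, y = 0, z = 33, d = sqrt(25 + 33^2),
                       dprime = 15)
  expect_equal(hd_at_point(mh, pt), 1.9475338, tolerance = 1e-6)

  # field-size factor is a plain multiplier
  mf <- toy_model(field_size_factor = 0.623)
  expect_equal(hd_at_point(mf, iso), 0.623 * hd_at_point(toy_model(), iso))
})

test_that("points at or behind the source plane are rejected", {
  m <- toy_model()
  behind <- tibble::tibble(x = 0, y = 0, z = -1, d = 1, dprime = 0)
  expect_error(hd_at_point(m, behind), "source plane")
  at_plane <- tibble::tibble(x = 5, y = 0, z = 0.05, d = 5, dprime = 0)
  expect_error(hd_at_point(m, at_plane), "source plane")
})

test_that("H/D is monotone in attenuation depth and radius", {
  m <- toy_model()
  # fixed geometry, increasing dprime
  dp <- seq(0, 40, by = 0.5)
  hd <- hd_at_point(m, tibble::tibble(x = 0, y = 0, z = 40, d = 40,
                                      dprime = dp))
  expect_true(all(diff(hd) <= 0))
  # fixed z and dprime, increasing lateral radius
  x <- seq(0, 30, by = 0.5)
  hd2 <- hd_at_point(m, tibble::tibble(x = x, y = 0, z = 40,
                                       d = sqrt(x^2 + 1600), dprime = 10))
  expect_true(all(diff(hd2) <= 0))
})

test_that("lateral width of each component grows linearly with z", {
  # single-component model in vacuum: hd(x, z) / hd(0, z) must equal the
  # closed-form Gaussian, whose 1/e radius is sigma*z*sqrt(2)/d_iso
  m <- suppressWarnings(neutron_model(
    1, 0, 33, 0, toy_components(C = c(1, 0, 0, 0), alpha = c(0, 0, 0, 0),
                                sigma = c(10, 1, 1, 1))))
  for (z in c(20, 40, 80)) {
    xe <- 10 * z * sqrt(2) / 33
    ratio <- hd_at_point(m, tibble::tibble(x = xe, y = 0, z = z,
                                           d = sqrt(xe^2 + z^2),
                                           dprime = 0)) /
      hd_at_point(m, tibble::tibble(x = 0, y = 0, z = z, d = z, dprime = 0))
    # divergence term cancels only at p = 0 (set above), leaving exp(-1)
    expect_equal(ratio, exp(-1), tolerance = 1e-12)
  }
})

test_that("grid evaluation equals pointwise evaluation at random voxels", {
  g <- random_grid(dims = c(16, 12, 10), spacing = 0.8,
                   origin = c(5, -5, -4), seed = 21)
  m <- toy_model()
  src <- c(0, 0, 0); ax <- c(1, 0, 0)
  hd <- hd_grid(m, g, source = src, axis = ax, isocenter = c(12, 0, 0))
  m2 <- m
  m2$dprime_iso <- attr(hd, "dprime_iso")
  set.seed(31)
  idx <- sample(prod(g$dims), 100)
  bf <- to_beam_frame(voxel_centers(g)[idx, , drop = FALSE], src, ax,
                      grid = g)
  expect_identical(as.numeric(hd$values)[idx], hd_at_point(m2, bf))
})

test_that("voxels behind the source plane score zero, with a count", {
  g <- voxel_grid(array(1, dim = c(10, 6, 6)), spacing = 1,
                  origin = c(-5, -3, -3))
  m <- toy_model()
  # source in the middle of the grid: upstream half must be zero
  expect_message(
    hd <- hd_grid(m, g, source = c(0, 0, 0), axis = c(1, 0, 0),
                  isocenter = c(3, 0, 0)),
    "behind the source")
  expect_gt(attr(hd, "n_behind_source"), 0)
  upstream <- voxel_centers(g)[, 1] < 0
  expect_true(all(hd$values[array(upstream, dim = g$dims)] == 0))
  expect_true(all(hd$values >= 0))
  expect_true(all(is.finite(hd$values)))

  # grid entirely upstream of the source: all zeros
  expect_message(
    hd0 <- hd_grid(m, g, source = c(20, 0, 0), axis = c(1, 0, 0),
                   isocenter = c(25, 0, 0), recompute_dprime_iso = FALSE))
  expect_true(all(hd0$values == 0))
})

test_that("equivalent dose scales H/D by the prescription", {
  g <- voxel_grid(array(3.33, dim = c(4, 4, 4)), spacing = 1,
                  value_kind = "mSv/Gy")
  sv <- neutron_equivalent_dose(g, 36)
  expect_equal(sv$values[1], 0.11988)   # 3.33 mSv/Gy * 36 Gy = 0.120 Sv
  expect_equal(sv$value_kind, "Sv")
  expect_true(all(neutron_equivalent_dose(g, 0)$values == 0))
  zero <- voxel_grid(array(0, dim = c(4, 4, 4)), spacing = 1,
                     value_kind = "mSv/Gy")
  expect_true(all(neutron_equivalent_dose(zero, 36)$values == 0))
  expect_error(neutron_equivalent_dose(g, -1), "non-negative")
  wrong <- voxel_grid(array(1, dim = c(4, 4, 4)), spacing = 1,
                      value_kind = "Gy")
  expect_error(neutron_equivalent_dose(wrong, 36), "mSv/Gy")
})
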