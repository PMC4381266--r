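test_that("spectrum weighting reproduces hand-computed cases", {
  # single bin: the weighted value collapses to that bin's H/D
  one <- tibble::tibble(energy = 160, n = 1, hd_iso = 5.0)
  expect_equal(weighted_hd_iso(one), 5.0)

  # two bins by hand: 0.5*2.0 + 1.0*3.0, n_max from the 140 MeV bin
  two <- tibble::tibble(energy = c(100, 140), n = c(0.5, 1.0),
                        hd_iso = c(2.0, 3.0))
  expect_equal(weighted_hd_iso(two), 4.0)

  # alternative n_max reading picks the largest count instead
  three <- tibble::tibble(energy = c(100, 140), n = c(2, 1),
                          hd_iso = c(2.0, 3.0))
  expect_equal(weighted_hd_iso(three), 7.0)
  expect_equal(weighted_hd_iso(three, n_max_rule = "max_count"), 3.5)
})

test_that("spectrum weighting is linear and scale-invariant in the counts", {
  set.seed(11)
  base <- tibble::tibble(energy = sort(runif(6, 80, 180)),
                         n = runif(6, 0.1, 2), hd_iso = runif(6, 0.5, 6))
  w <- weighted_hd_iso(base)
  # common rescaling of all n_j cancels against n_max
  for (k in c(0.2, 3, 117)) {
    scaled <- dplyr::mutate(base, n = n * k)
    expect_equal(weighted_hd_iso(scaled), w)
  }
  # linear in each hd_iso_j
  doubled <- dplyr::mutate(base, hd_iso = 2 * hd_iso)
  expect_equal(weighted_hd_iso(doubled), 2 * w)
  # additive over hd_iso contributions
  a <- dplyr::mutate(base, hd_iso = hd_iso * c(1, 0, 1, 0, 1, 0))
  b <- dplyr::mutate(base, hd_iso = hd_iso * c(0, 1, 0, 1, 0, 1))
  expect_equal(weighted_hd_iso(a) + weighted_hd_iso(b), w)
})

test_that("spectrum validation rejects degenerate inputs", {
  expect_error(weighted_hd_iso(tibble::tibble(energy = numeric(),
                                              n = numeric(),
                                              hd_iso = numeric())),
               "empty")
  expect_error(weighted_hd_iso(tibble::tibble(energy = c(100, 90),
                                              n = c(1, 1),
                                              hd_iso = c(1, 1))),
               "increasing")
  expect_error(weighted_hd_iso(tibble::tibble(energy = c(100, 140),
                                              n = c(1, 0),
                                              hd_iso = c(1, 1))),
               "n_max")
  expect_error(weighted_hd_iso(tibble::tibble(energy = 100, n = -1,
                                              hd_iso = 1)))
})

test_that("field-size correction is the blocked-area fraction", {
  tot <- matrix(TRUE, 10, 10)
  none_open <- matrix(FALSE, 10, 10)
  expect_equal(field_size_correction(none_open, tot), 1.0)
  expect_equal(field_size_correction(tot, tot), 0.0)
  half <- none_open; half[1:5, ] <- TRUE
  expect_equal(field_size_correction(half, tot), 0.5)

  # monotone: opening pixels can only lower the factor
  set.seed(3)
  open <- none_open
  prev <- 1
  for (i in 1:20) {
    open[sample(100, 1)] <- TRUE
    f <- field_size_correction(open, tot)
    expect_lte(f, prev)
    prev <- f
  }

  expect_error(field_size_correction(none_open, matrix(FALSE, 10, 10)),
               "empty")
  bad_open <- matrix(TRUE, 10, 10)
  tot2 <- matrix(FALSE, 10, 10); tot2[1:5, ] <- TRUE
  expect_error(field_size_correction(bad_open, tot2), "within")
})

test_that("model validation enforces parameter ranges and completeness", {
  expect_s3_class(toy_model(), "neutron_model")
  expect_error(toy_model(hd_iso = 0), "hd_iso")
  expect_error(toy_model(p = -0.1), "p must")
  expect_error(toy_model(d_iso = -1), "d_iso")
  expect_error(toy_model(components = toy_components(sigma = c(0, 1, 1, 1))),
               "sigma")
  expect_error(toy_model(components = toy_components(C = c(-1, 1, 1, 1))),
               "C must")
  missing_thermal <- toy_components()[1:3, ]
  expect_error(toy_model(components = missing_thermal), "thermal")
  dup <- toy_components()
  dup$label[4] <- "evaporation"
  expect_error(toy_model(components = dup))
  # weights far from 1 warn (isocenter value becomes inconsistent)
  expect_warning(toy_model(components = toy_components(C = c(1, 1, 1, 1))),
                 "sum")
})

test_that("model config files load, with hd_iso delegated to the spectrum", {
  m <- default_neutron_model()
  expect_equal(m$hd_iso, 3.68)
  expect_equal(m$d_iso, 33)
  expect_equal(m$field_size_factor, 1)
  expect_setequal(m$components$label, component_labels)

  ms <- read_neutron_model(
    system.file("extdata", "neutron_model_spectrum_example.yaml",
                package = "straydose"))
  expect_equal(ms$hd_iso, weighted_hd_iso(attr(ms, "spectrum")))

  # config with a missing component names the missing label
  cfg <- list(model = list(hd_iso = 2, p = 1, d_iso = 33, dprime_iso = 5),
              components = list(
                `intranuclear-cascade` = list(C = 1, alpha = .1, sigma = 5),
                evaporation = list(C = 0, alpha = .1, sigma = 5),
                epithermal = list(C = 0, alpha = .1, sigma = 5)))
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  expect_error(suppressWarnings(read_neutron_model(f)), "thermal")

  # neither hd_iso nor spectrum
  cfg$model$hd_iso <- NULL
  cfg$components$thermal <- list(C = 0, alpha = .1, sigma = 5)
  yaml::write_yaml(cfg, f)
  expect_error(read_neutron_model(f), "spectrum")
})
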