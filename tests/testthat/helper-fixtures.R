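# fixtures are built in code; nothing is read from disk

component_labels <- c("intranuclear-cascade", "evaporation",
                      "epithermal", "thermal")

toy_components <- function(C = c(0.4, 0.35, 0.15, 0.1),
                           alpha = c(0.06, 0.1, 0.02, 0.01),
                           sigma = c(20, 35, 60, 100)) {
  tibble::tibble(label = component_labels, C = C, alpha = alpha,
                 sigma = sigma)
}

toy_model <- function(hd_iso = 3.68, p = 0.9, d_iso = 33, dprime_iso = 7.5,
                      components = toy_components(), ...) {
  neutron_model(hd_iso, p, d_iso, dprime_iso, components, ...)
}

# heterogeneous random-density grid for tracer tests
random_grid <- function(dims = c(12, 10, 8), spacing = 0.7,
                        origin = c(-2, -3, -1), seed = 7,
                        range = c(0.05, 1.8)) {
  set.seed(seed)
  voxel_grid(array(runif(prod(dims), range[1], range[2]), dim = dims),
             spacing, origin)
}

# independent fine-step WEPL oracle: midpoint sampling at `step` cm.
# The default step (2 um) keeps the oracle's own discretisation error an
# order of magnitude below the 1e-3 cm comparison band even on rays that
# cross many high-contrast voxel faces.
wepl_oracle <- function(grid, p0, p1, step = 2e-4, outside = 0.001) {
  L <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(L / step))
  t <- (seq_len(n) - 0.5) / n
  pts <- outer(t, p1 - p0) + matrix(p0, n, 3, byrow = TRUE)
  idx <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")
  ijk <- floor(idx)
  inside <- ijk[, 1] >= 0 & ijk[, 1] < grid$dims[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid$dims[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid$dims[3]
  dens <- rep(outside, n)
  lin <- ijk[inside, 1] + grid$dims[1] *
    (ijk[inside, 2] + grid$dims[2] * ijk[inside, 3]) + 1
  dens[inside] <- as.numeric(grid$values)[lin]
  sum(dens) * L / n
}

# independent piecewise SOBP evaluation (deliberately separate from the
# package's implementation)
sobp_oracle <- function(depth, range, modulation, entrance = 0.75,
                        falloff = 0.6) {
  start <- max(range - modulation, 0)
  s <- falloff / 5
  erfc2 <- function(x) 2 * pnorm(-x * sqrt(2))
  vapply(seq_along(depth), function(i) {
    d <- depth[i]
    if (d < start) entrance + (1 - entrance) * d / start
    else if (d <= range) 1
    else {
      f0 <- 0.5 * erfc2((-falloff / 2) / (s * sqrt(2)))
      0.5 * erfc2(((d - range) - falloff / 2) / (s * sqrt(2))) / f0
    }
  }, numeric(1))
}

# small, fast water-box scene reused across tests
coarse_water_scene <- function(spacing = 0.5) {
  wb <- make_water_box(spacing = spacing)
  list(wb = wb, plan = water_box_plan())
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
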