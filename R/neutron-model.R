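COMPONENT_LABELS <- c("intranuclear-cascade", "evaporation",
                      "epithermal", "thermal")

#' Analytical neutron source model
#'
#' Container for the four-component analytical model of leakage-neutron
#' equivalent dose per prescribed proton dose, H/D. The neutron fluence is
#' treated as emanating from a virtual point source on the central axis at
#' the downstream face of the patient collimator; each component i
#' (intranuclear-cascade, evaporation, epithermal, thermal) carries a weight
#' `C`, an attenuation coefficient `alpha` (per cm water-equivalent) and a
#' lateral Gaussian width `sigma` (cm, defined at the isocenter plane).
#'
#' The per-point model is
#' \deqn{H/D = f \cdot (H/D)_{iso} (d/d_{iso})^{-p} \sum_{i=1}^{4}
#'   C_i e^{-\alpha_i (d' - d'_{iso})}
#'   e^{-(x^2+y^2) d_{iso}^2 / (2 \sigma_i^2 z^2)}}
#' with `f` the field-size correction factor.
#'
#' The component weights are expected to sum to about 1 (at the isocenter
#' point the model collapses to `hd_iso * sum(C)`); a deviation beyond 1e-3
#' triggers a warning, not an error, since published fits need not be
#' normalised.
#'
#' @param hd_iso (H/D) at isocenter, mSv per Gy; `> 0`.
#' @param p dimensionless power-law divergence exponent; `>= 0`.
#' @param d_iso geometric source-to-isocenter distance, cm; `> 0`.
#' @param dprime_iso water-equivalent source-to-isocenter pathlength, cm;
#'   `>= 0`.
#' @param components data frame with columns `label`, `C`, `alpha`, `sigma`:
#'   exactly one row per component label.
#' @param field_size_factor dimensionless multiplier in `[0, 1]` accounting
#'   for partial collimator blocking (see [field_size_correction()]).
#' @return A validated `neutron_model` object.
#' @export
neutron_model <- function(hd_iso, p, d_iso, dprime_iso, components,
                          field_size_factor = 1) {
  components <- tibble::as_tibble(components)
  m <- structure(
    list(hd_iso = as.numeric(hd_iso), p = as.numeric(p),
         d_iso = as.numeric(d_iso), dprime_iso = as.numeric(dprime_iso),
         components = components,
         field_size_factor = as.numeric(field_size_factor)),
    class = "neutron_model"
  )
  validate_neutron_model(m)
}

#' @rdname neutron_model
#' @param model object to validate.
#' @export
validate_neutron_model <- function(model) {
  stopifnot(inherits(model, "neutron_model"))
  scal <- c(hd_iso = model$hd_iso, p = model$p, d_iso = model$d_iso,
            dprime_iso = model$dprime_iso, fsf = model$field_size_factor)
  if (anyNA(scal) || any(!is.finite(scal)))
    stop("model scalars must be finite", call. = FALSE)
  if (model$hd_iso <= 0) stop("hd_iso must be > 0", call. = FALSE)
  if (model$p < 0) stop("p must be >= 0", call. = FALSE)
  if (model$d_iso <= 0) stop("d_iso must be > 0", call. = FALSE)
  if (model$dprime_iso < 0) stop("dprime_iso must be >= 0", call. = FALSE)
  if (model$field_size_factor < 0 || model$field_size_factor > 1)
    stop("field_size_factor must be in [0, 1]", call. = FALSE)
  comp <- model$components
  if (!all(c("label", "C", "alpha", "sigma") %in% names(comp)))
    stop("components need columns label, C, alpha, sigma", call. = FALSE)
  missing <- setdiff(COMPONENT_LABELS, comp$label)
  if (length(missing))
    stop("missing neutron component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(comp$label, COMPONENT_LABELS)
  if (length(extra) || anyDuplicated(comp$label))
    stop("components must be exactly one row per label in {",
         paste(COMPONENT_LABELS, collapse = ", "), "}", call. = FALSE)
  with(comp, {
    if (anyNA(c(C, alpha, sigma)) || any(!is.finite(c(C, alpha, sigma))))
      stop("component parameters must be finite", call. = FALSE)
    if (any(C < 0)) stop("component weights C must be >= 0", call. = FALSE)
    if (any(alpha < 0)) stop("alpha must be >= 0", call. = FALSE)
    if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  })
  csum <- sum(comp$C)
  if (abs(csum - 1) > 1e-3)
    warning(sprintf(
      "component weights sum to %.4f (not 1): hd_iso is then inconsistent %s",
      csum, "with the model's own value at isocenter"), call. = FALSE)
  model
}

#' @export
print.neutron_model <- function(x, ...) {
  cat(sprintf(
    "<neutron_model> hd_iso = %.4g mSv/Gy, p = %.3g, d_iso = %.4g cm,\n",
    x$hd_iso, x$p, x$d_iso))
  cat(sprintf("  dprime_iso = %.4g cm, field_size_factor = %.3f, sum(C) = %.4f\n",
              x$dprime_iso, x$field_size_factor, sum(x$components$C)))
  print(x$components)
  invisible(x)
}

#' Spectrum-weighted (H/D) at isocenter
#'
#' Combines monoenergetic isocenter H/D values over the energy bins of a
#' modulated beam: `(1/n_max) * sum_j hd_iso_j * n_j`, where `n_max` is by
#' default the proton count of the highest-energy bin (the pristine peak of
#' the modulated beam). The alternative reading — the largest count in any
#' bin — is available via `n_max_rule = "max_count"`.
#'
#' @param spectrum data frame with columns `energy` (MeV, strictly
#'   increasing), `n` (proton count weight, `>= 0`) and `hd_iso` (mSv/Gy per
#'   bin).
#' @param n_max_rule `"max_energy"` (default) or `"max_count"`.
#' @return Weighted (H/D)_iso in mSv/Gy.
#' @export
weighted_hd_iso <- function(spectrum, n_max_rule = c("max_energy",
                                                     "max_count")) {
  n_max_rule <- match.arg(n_max_rule)
  spectrum <- tibble::as_tibble(spectrum)
  if (!all(c("energy", "n", "hd_iso") %in% names(spectrum)))
    stop("spectrum needs columns energy, n, hd_iso", call. = FALSE)
  if (nrow(spectrum) == 0L) stop("spectrum is empty", call. = FALSE)
  if (any(!is.finite(spectrum$energy)) || any(diff(spectrum$energy) <= 0))
    stop("energies must be finite and strictly increasing", call. = FALSE)
  if (any(spectrum$n < 0) || any(!is.finite(spectrum$n)))
    stop("bin counts n must be finite and >= 0", call. = FALSE)
  n_max <- switch(n_max_rule,
                  max_energy = spectrum$n[nrow(spectrum)],
                  max_count = max(spectrum$n))
  if (n_max == 0)
    stop("n_max is zero: the maximum-energy bin must have n > 0",
         call. = FALSE)
  sum(spectrum$hd_iso * spectrum$n) / n_max
}

#' Field-size correction factor
#'
#' Ratio of blocked to total area of the proton field incident on the
#' patient-specific collimator. Source-model parameters are calibrated for a
#' closed collimator, so an open aperture produces proportionally fewer
#' collimator neutrons; the factor multiplies `hd_iso`.
#'
#' @param aperture_open logical matrix: `TRUE` where the collimator is open.
#' @param total_field logical matrix (same shape): the field footprint on the
#'   collimator. The open region must lie inside the total field.
#' @return Blocked-area fraction in `[0, 1]` (1 = fully blocked).
#' @export
field_size_correction <- function(aperture_open, total_field) {
  stopifnot(is.logical(aperture_open), is.logical(total_field),
            all(dim(aperture_open) == dim(total_field)))
  tot <- sum(total_field)
  if (tot == 0) stop("total field region is empty", call. = FALSE)
  if (any(aperture_open & !total_field))
    stop("aperture open region must lie within the total field",
         call. = FALSE)
  sum(total_field & !aperture_open) / tot
}

#' Load a neutron source model from a YAML configuration
#'
#' The file has a `model` section (`p`, `d_iso`, `dprime_iso`, optional
#' `hd_iso` and `field_size_factor`), a `components` section with one entry
#' per label (`C`, `alpha`, `sigma`), and optionally a `spectrum` list of
#' `{energy, n, hd_iso}` records. `hd_iso` may be given directly or computed
#' from the spectrum via [weighted_hd_iso()]; at least one of the two must be
#' present.
#'
#' @param path YAML file path.
#' @param n_max_rule passed to [weighted_hd_iso()] when a spectrum is used.
#' @return A validated [neutron_model()]; any packaged spectrum is attached
#'   as attribute `"spectrum"`.
#' @export
read_neutron_model <- function(path, n_max_rule = "max_energy") {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model))
    stop("config is missing the [model] section", call. = FALSE)
  if (is.null(cfg$components))
    stop("config is missing the [components] section", call. = FALSE)
  comp <- dplyr::bind_rows(lapply(names(cfg$components), function(lbl) {
    e <- cfg$components[[lbl]]
    tibble::tibble(label = lbl, C = e$C, alpha = e$alpha, sigma = e$sigma)
  }))
  spectrum <- NULL
  hd_iso <- cfg$model$hd_iso
  if (!is.null(cfg$spectrum)) {
    spectrum <- dplyr::bind_rows(lapply(cfg$spectrum, function(rec) {
      # YAML 1.1 reads a bare `n` key as the boolean FALSE; undo that
      names(rec)[names(rec) %in% c("FALSE", "false")] <- "n"
      tibble::as_tibble(rec)
    }))
    if (is.null(hd_iso)) hd_iso <- weighted_hd_iso(spectrum, n_max_rule)
  }
  if (is.null(hd_iso))
    stop("config must supply either model.hd_iso or a spectrum",
         call. = FALSE)
  m <- neutron_model(
    hd_iso = hd_iso, p = cfg$model$p, d_iso = cfg$model$d_iso,
    dprime_iso = cfg$model$dprime_iso, components = comp,
    field_size_factor = cfg$model$field_size_factor %||% 1
  )
  attr(m, "spectrum") <- spectrum
  m
}

#' Packaged illustrative neutron model
#'
#' The fitted source-model parameters used clinically are facility-specific
#' and not distributable; the packaged set is an illustrative, non-clinical
#' parameterisation with physically plausible orderings (fast cascade
#' neutrons forward-peaked and penetrating; thermal neutrons diffuse and
#' strongly attenuated laterally wide), intended for tests, phantom studies
#' and as a template for facility-calibrated values.
#'
#' @param ... passed to [read_neutron_model()].
#' @return A [neutron_model()].
#' @export
default_neutron_model <- function(...) {
  read_neutron_model(
    system.file("extdata", "neutron_model_default.yaml",
                package = "straydose", mustWork = TRUE), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
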