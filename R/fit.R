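#' Fit the analytical neutron model to sampled H/D values
#'
#' Least-squares refit of the shape parameters — the divergence exponent `p`
#' and the four components' weights `C`, attenuation coefficients `alpha`
#' and lateral widths `sigma` — from sampled H/D values in beam coordinates.
#' The plan-level scalars (`hd_iso`, `d_iso`, `dprime_iso`, field-size
#' factor) are held fixed at the reference model's values. Intended for
#' verification (an engine-generated noiseless grid must return its own
#' parameters) and for exploratory calibration against external dose maps.
#'
#' Identifiability requires samples spanning distinct `dprime` and lateral
#' offsets, and reasonably separated component parameters; starting values
#' default to the reference model's.
#'
#' @param data data frame with columns `x, y, z, d, dprime, hd` (cm and
#'   mSv/Gy), e.g. voxel samples of an H/D grid joined with
#'   [to_beam_frame()] output.
#' @param model0 reference [neutron_model()] supplying the fixed scalars and
#'   default starting values.
#' @param start optional named list overriding starting values: `p`, and
#'   vectors `C`, `alpha`, `sigma` of length 4 (in the order of
#'   `model0$components`).
#' @param ... passed to [minpack.lm::nlsLM()].
#' @return An object of class `hd_fit`; see [tidy.hd_fit()] and
#'   [glance.hd_fit()].
#' @export
fit_hd_model <- function(data, model0, start = NULL, ...) {
  data <- tibble::as_tibble(data)
  need <- c("x", "y", "z", "d", "dprime", "hd")
  if (!all(need %in% names(data)))
    stop("data needs columns ", paste(need, collapse = ", "), call. = FALSE)
  comp <- model0$components
  st <- list(p = model0$p, C = comp$C, alpha = comp$alpha,
             sigma = comp$sigma)
  if (!is.null(start)) st[names(start)] <- start
  start_vec <- c(p = st$p,
                 stats::setNames(st$C, paste0("C", 1:4)),
                 stats::setNames(st$alpha, paste0("a", 1:4)),
                 stats::setNames(st$sigma, paste0("s", 1:4)))
  scale0 <- model0$field_size_factor * model0$hd_iso
  fit <- minpack.lm::nlsLM(
    hd ~ scale0 * (d / d_iso)^(-p) * (
      C1 * exp(-a1 * (dprime - dp_iso) - (x^2 + y^2) * d_iso^2 /
                 (2 * s1^2 * z^2)) +
      C2 * exp(-a2 * (dprime - dp_iso) - (x^2 + y^2) * d_iso^2 /
                 (2 * s2^2 * z^2)) +
      C3 * exp(-a3 * (dprime - dp_iso) - (x^2 + y^2) * d_iso^2 /
                 (2 * s3^2 * z^2)) +
      C4 * exp(-a4 * (dprime - dp_iso) - (x^2 + y^2) * d_iso^2 /
                 (2 * s4^2 * z^2))),
    data = cbind(data, d_iso = model0$d_iso, dp_iso = model0$dprime_iso,
                 scale0 = scale0),
    start = as.list(start_vec),
    lower = c(0, rep(0, 4), rep(0, 4), rep(1e-3, 4)),
    control = minpack.lm::nls.lm.control(maxiter = 200),
    ...)
  structure(list(fit = fit, model0 = model0, n = nrow(data),
                 labels = comp$label),
            class = "hd_fit")
}

#' @export
print.hd_fit <- function(x, ...) {
  cat("<hd_fit> analytical neutron-model refit\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy / summarise a neutron-model refit
#'
#' `tidy()` returns one row per fitted parameter (`p`, then per-component
#' `C`, `alpha`, `sigma` tagged with the component label) with estimates and
#' standard errors; `glance()` returns a one-row fit summary.
#'
#' @param x an `hd_fit` from [fit_hd_model()].
#' @param ... ignored.
#' @return A tibble.
#' @export
tidy.hd_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  terms <- rownames(s)
  comp_of <- function(t) {
    i <- suppressWarnings(as.integer(substring(t, 2)))
    ifelse(t == "p", NA_character_, x$labels[i])
  }
  kind <- c(p = "p", C = "C", a = "alpha", s = "sigma")
  tibble::tibble(
    term = terms,
    parameter = ifelse(terms == "p", "p", kind[substring(terms, 1, 1)]),
    component = vapply(terms, comp_of, character(1)),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"]
  )
}

#' @rdname tidy.hd_fit
#' @export
glance.hd_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    rss = sum(stats::residuals(x$fit)^2),
    sigma = summary(x$fit)$sigma,
    converged = x$fit$convInfo$isConv,
    iterations = x$fit$convInfo$finIter
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
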