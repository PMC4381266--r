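Package: straydose
Title: Out-of-Field Neutron Equivalent Dose for Passively Scattered Proton
    Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical engine for out-of-field (stray) neutron equivalent
    dose in passively scattered proton radiotherapy.  Implements a
    four-component neutron source model with power-law divergence and
    exponential attenuation along ray-traced water-equivalent pathlengths
    through voxelized heterogeneous anatomy, together with a simplified
    deterministic spread-out-Bragg-peak proton dose engine, phantom
    generators for a water-box and a thorax-like geometry, and reporting
    utilities (structure dose statistics, dose-volume histograms, isodose
    contours) so combined proton plus neutron equivalent-dose distributions
    can be computed and summarised for phantoms and patient-like volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
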