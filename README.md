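# straydose

Out-of-field (stray) neutron equivalent dose for passively scattered proton
radiotherapy.

Treatment planning systems compute the therapeutic proton dose but ignore
the leakage neutrons produced in the treatment head — mostly in the
patient-specific collimator — even though those neutrons dominate the
equivalent dose to organs far from the field and hence the predicted risk of
radiogenic late effects there. `straydose` implements a fast analytical
engine for that neutron equivalent dose on voxelized, heterogeneous
CT-like anatomy, together with a simplified deterministic passive-scattering
proton dose engine, so combined proton + neutron equivalent-dose
distributions and organ statistics can be computed for phantoms and
patient-like volumes in seconds on one CPU.

## The model

Neutron equivalent dose per prescribed proton dose at a point expressed in
beam coordinates (lateral offsets *x*, *y*; axial distance *z* from the
virtual neutron source at the downstream face of the collimator; geometric
source distance *d*; water-equivalent pathlength *d*′) is

    H/D(x,y,z) = f · (H/D)_iso · (d/d_iso)^(-p)
                 · Σ_{i=1..4} C_i · exp[-α_i (d′ - d′_iso)]
                             · exp[-(x² + y²) d_iso² / (2 σ_i² z²)]

with one term per neutron component (intranuclear-cascade, evaporation,
epithermal, thermal): `C_i` weights, `α_i` attenuation per cm
water-equivalent, `σ_i` lateral Gaussian widths defined at the isocenter
plane and diverging linearly with `z`. `(H/D)_iso` is the plan-level value
at isocenter, either given directly or spectrum-weighted over energy bins,
`(H/D)_iso = (1/n_max) Σ_j (H/D)_iso,j n_j`, and `f` is a field-size
correction (the blocked-to-total area ratio of the collimator, since the
model is calibrated against a closed collimator). The pathlength `d′` is
obtained by exact Siddon-style ray tracing from the virtual source through
the voxel grid, with Hounsfield units converted to relative water-equivalent
density by a piecewise-linear calibration table.

The proton side is a closed-form surrogate for a pencil-beam engine:
beam's-eye-view aperture projection of the target, a range-modulation width
taken from the radiological extent of the target, a passive-scattering
surrogate target (PTV_PS), and per-ray spread-out-Bragg-peak depth dose
times an error-function lateral penumbra, normalised to the prescription at
the isocenter.

Fitted model parameters are facility-specific; the package ships a clearly
labelled illustrative set (`inst/extdata/neutron_model_default.yaml`) and
reads user-supplied YAML calibrations (`read_neutron_model()`).

## Worked example

```r
library(straydose)

wb    <- make_water_box()                    # 30 x 15 x 15 cm^3 water box,
plan  <- water_box_plan(prescription = 36)   #   5-cm target at 7.5 cm depth
ptv_ps <- build_ptv_ps(wb$target, wb$anatomy, plan)
proton <- proton_dose_grid(plan, wb$anatomy, ptv_ps)

model <- default_neutron_model()             # illustrative parameter set
nsrc  <- plan$source + plan$collimator_z * plan$axis
hd    <- hd_grid(model, wb$anatomy, source = nsrc, axis = plan$axis,
                 isocenter = wb$isocenter)
neutron  <- neutron_equivalent_dose(hd, plan$prescription)
combined <- combine_equivalent_dose(proton, neutron)

structure_stats(combined, wb$target, plan$prescription)
#> # A tibble: 1 × 7
#>   structure n_voxels mean_Sv sd_Sv min_Sv max_Sv pct_of_prescription
#> 1 target        4224    35.9 0.399   34.4   36.2                99.7

structure_stats(neutron, wb$target, plan$prescription)
#> # A tibble: 1 × 7
#>   structure n_voxels mean_Sv  sd_Sv min_Sv max_Sv pct_of_prescription
#> 1 target        4224   0.133 0.0135  0.107  0.165               0.369
```

The target receives 99.7% of the 36 Gy prescription as combined equivalent
dose; the neutron contribution inside the target is 0.37% of the
prescription (0.13 Sv), and outside the field it falls off with distance,
attenuation and divergence rather than dropping to zero as a protons-only
calculation would suggest. The auto-derived modulation width for this plan
is 5.00 cm water-equivalent, and the traced source-to-isocenter pathlength
is 7.53 cm (7.5 cm of water plus the upstream air gap).

`run_pipeline()` performs the whole chain (phantom → PTV_PS → proton dose →
neutron dose → combined dose → statistics, DVHs, NIfTI rasters, manifest)
for the water box or for a heterogeneous thorax-like phantom with lungs,
spine, mediastinal target and a far-field thyroid; `inst/cli/straydose` is
a thin command-line front end over the same functions. DVHs, isodose
contours and slice colorwash plots come from `dvh()`, `isodose_bands()`,
`plot_dvh()` and `plot_dose_slice()`; `fit_hd_model()` refits the model
shape parameters from sampled H/D values (with `tidy()`/`glance()`
methods).

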