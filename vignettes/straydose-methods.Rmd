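---
title: "Methods: analytical stray-neutron equivalent dose on voxelized anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analytical stray-neutron equivalent dose on voxelized anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`straydose` computes the equivalent dose delivered by leakage neutrons
during passively scattered proton therapy, outside (and inside) the
therapeutic field, on voxelized heterogeneous anatomy. The neutrons are
modelled as emanating from a single virtual point source on the central
axis at the downstream face of the patient-specific collimator — the place
where the large majority of treatment-head neutrons that reach the patient
originate. Per prescribed proton dose $D$ at the isocenter, the neutron
equivalent dose $H$ at a point with beam coordinates $(x, y, z)$, geometric
source distance $d$ and water-equivalent source pathlength $d'$ is

$$
\frac{H}{D} = f \,\Big(\frac{H}{D}\Big)_{\mathrm{iso}}
\Big(\frac{d}{d_{\mathrm{iso}}}\Big)^{-p}
\sum_{i=1}^{4} C_i\,
e^{-\alpha_i\,(d' - d'_{\mathrm{iso}})}\,
e^{-(x^2+y^2)\, d_{\mathrm{iso}}^2 / (2\sigma_i^2 z^2)} .
$$

The four components describe the physically distinct neutron populations
(intranuclear-cascade, evaporation, epithermal, thermal), each with a
weight $C_i$ (dimensionless), an attenuation coefficient $\alpha_i$ (per cm
water-equivalent) and a lateral Gaussian width $\sigma_i$ (cm, defined at
the isocenter plane; the $d_{\mathrm{iso}}^2/z^2$ scaling makes each
component's lateral width grow linearly with axial distance, i.e. the
fluence diverges from the source). $f \in [0,1]$ is a field-size
correction: the model parameters are calibrated for a closed collimator, so
an open aperture produces proportionally fewer collimator neutrons and $f$
is the blocked-to-total area fraction of the field on the collimator
(`field_size_correction()`).

Two assumptions matter for interpretation. First, attenuation is
water-equivalent: tissue is treated as water of varying density, not as its
elemental composition, so the model is least accurate in air and lung where
hydrogen-driven recoil-proton dose differs most from scaled water. Second,
all neutrons come from the collimator plane; neutrons produced inside the
patient are not modelled, which restricts validity to passive scattering.

### Plan-level inputs

$(H/D)_{\mathrm{iso}}$ may be given directly or computed from a
monoenergetic table over the energy bins of the modulated beam,
$(H/D)_{\mathrm{iso}} = n_{\max}^{-1}\sum_j (H/D)_{\mathrm{iso},j}\, n_j$
(`weighted_hd_iso()`). We read $n_{\max}$ as the proton count of the
highest-*energy* bin — the pristine peak of the modulated beam, which is the
natural normalisation for a modulation wheel — and expose
`n_max_rule = "max_count"` for the alternative largest-count reading, since
published descriptions do not always disambiguate the two.

$d'_{\mathrm{iso}}$ is not a free parameter: by default `hd_grid()`
recomputes it per call by tracing the source→isocenter ray through the same
anatomy being scored, which keeps the attenuation reference consistent.
A configured value can be forced (`recompute_dprime_iso = FALSE`) for
water-tank reproductions.

The component parameters themselves are facility- and nozzle-specific fits
to Monte Carlo data and are not redistributable; the packaged default set
(`inst/extdata/neutron_model_default.yaml`) is an **illustrative,
non-clinical** stand-in chosen once from physical orderings: cascade
neutrons forward-peaked ($\sigma$ small) and penetrating, evaporation
neutrons attenuated fastest, epithermal/thermal components laterally
diffuse with weak residual attenuation, weights summing to 1, and a
divergence exponent near but below 1 (a bare point source would give
$p = 2$ in fluence; dose response and in-scatter flatten the effective
power law). Component weights that do not sum to 1 are legal (published
fits need not be normalised) but trigger a warning, because at the
isocenter point the model then contradicts its own $(H/D)_{\mathrm{iso}}$.

## Ray tracing

`radiological_pathlength()` performs exact parametric (Siddon-style)
traversal: per traversed voxel, chord length × relative density, summed
along the segment. Implementation choices:

* voxels are half-open boxes `[origin + i·spacing, origin + (i+1)·spacing)`
  with 0-based indices in the compiled core; chords are attributed by their
  *midpoint*, so rays through faces, edges or corners are handled
  deterministically and zero-length boundary chords are dropped;
* segments outside the grid contribute with a configurable
  `outside_density` (default 0.001, air), matching a source that sits
  upstream of the patient in air — this also answers how air gaps enter
  $d'$: as near-zero water-equivalent depth;
* Hounsfield units convert to relative density through a piecewise-linear,
  end-clamped table; the packaged default (−1000 → 0.001, 0 → 1.0,
  100 → 1.05, 1500 → 1.6) is a generic stand-in for a clinic-calibrated
  curve and the table is user-replaceable (`hu_table()`,
  `read_hu_table()`).

The traversal is verified three ways in the test suite: chord lengths must
sum to the clipped in-grid segment length to 1e-9 relative; pathlengths
must agree with an independent fine-step midpoint-integration oracle within
1e-3 cm on 200 random rays over a random high-contrast grid (the oracle
samples every 2 µm so its own discretisation error stays an order of
magnitude below that band); and homogeneous-water pathlengths must equal
geometric lengths exactly.

## Grid evaluation and numerical guards

`hd_grid()` evaluates the model at every voxel center (no sub-voxel
averaging — each CT voxel is one calculation point). The lateral term
diverges as $z \to 0$, and the model only describes the forward half-space,
so voxels with $z \le z_{\min}$ (default 1 mm beyond the source plane)
score zero and are counted in an attribute; the point-level API treats them
as errors. Exponents are clamped before exponentiation so extreme
configurations overflow to finite values, and below-underflow contributions
flush to zero. Grid evaluation is deterministic, order-independent, and
bit-identical to the pointwise evaluator (tested on random voxels).

`fit_hd_model()` refits $(p, C_i, \alpha_i, \sigma_i)$ from sampled H/D
values by Levenberg–Marquardt least squares with the plan-level scalars
fixed. The 13 parameters are only identifiable when the samples span
distinct $d'$ at fixed geometry (a heterogeneous medium) and when the
component scales are separated; a noiseless engine-generated grid with
well-separated parameters is recovered to machine precision, which is the
package's strongest internal consistency check of engine and model.

## The proton surrogate

The pencil-beam optimizer of a clinical planning system is deliberately
replaced by a closed-form surrogate — the scientific content here is the
*neutron* engine, and the proton side only needs the correct in-field /
out-of-field behaviour. The chain is:

1. **Aperture** (`project_aperture()`): a collimator-plane pixel is open
   iff the divergent ray through its center intersects the target — the
   beam's-eye-view silhouette, no margin. Pixel spacing defaults to 0.2 cm
   and should be kept below the projected voxel size.
2. **Modulation width** (`modulation_width()`): the spread-out Bragg peak
   must cover the target's radiological extent. "Maximal difference between
   the radiological depths of the proximal and distal edges" admits two
   readings; the default is the conservative global envelope
   $\max_\mathrm{rays}(\mathrm{distal}) - \min_\mathrm{rays}(\mathrm{proximal})$,
   with `reading = "per_ray"` for the largest single-ray thickness.
3. **PTV_PS** (`build_ptv_ps()`): voxels inside the aperture whose
   radiological depth lies within the modulation band ending at their
   ray's distal target edge. Membership uses each voxel's own ray where it
   intersects the target (this guarantees the target is always contained
   in homogeneous media) and the band is widened proximally by half a
   voxel's water-equivalent thickness so that a zero-modulation band
   degenerates to the distal-edge shell instead of the empty set; a 1e-4 cm
   epsilon absorbs traversal round-off. The distal edge is never extended.
4. **Dose** (`proton_dose_grid()`): per voxel,
   prescription × SOBP(depth) × P(lateral). The per-ray range is the distal
   PTV_PS depth of the voxel's ray (conformal distal coverage by
   construction; the nominal energy and range shifter are bookkeeping).
   The SOBP is flat (=1) over the modulation interval, ramps linearly from
   an entrance plateau (default 0.75 of plateau dose — a typical
   entrance-to-SOBP ratio for mid-range modulated beams) and falls off
   distally along an error-function ramp of width 0.6 cm water-equivalent,
   continuous at the distal edge and below 1e-5 within 1 cm.

The lateral penumbra is an error function of the signed distance to the
aperture edge, with $\sigma_{\mathrm{pen}}$ = 0.5 cm at the isocenter plane
and diverging with $z$ (the divergence of the offset and of $\sigma$
cancel, so the profile depends only on the isocenter-scaled distance). Its
50% level sits `penumbra_margin` = 0.8 cm *outside* the geometric field
edge. This is the analytical analogue of the aperture margin a clinical
plan adds around the target: with the margin at zero, voxels on the target
silhouette would sit at the 50% level and target coverage would drop to
~95%. The margin is the largest value for which the dose 3 cm outside the
field edge still stays below $10^{-5}$ of the central dose
($\tfrac12\,\mathrm{erfc}\!\big((3-0.8)/(0.5\sqrt2)\big) \approx 5\times10^{-6}$),
which pins both design requirements simultaneously; both parameters are
config-exposed (`sobp_params()`). A hard cutoff zeroes dose beyond 3 cm
(collimator scale) outside the aperture. Proton equivalent dose uses a
radiation weighting factor of 1.

With these defaults the water-box plan delivers the prescription at the
isocenter to within 0.5%, a mean target dose of 99.3% of prescription,
$4\times10^{-4}$% of prescription 3 cm outside the field edge at target
depth, and $<10^{-5}$ of prescription 1 cm beyond the distal edge — the
figures `scripts/acceptance.R` recomputes.

## Phantoms

`make_water_box()` builds the 30 × 15 × 15 cm³ water box with a 5-cm
spherical target at 7.5 cm depth (0.25 cm voxels by default; sphere
voxelization error < 2%). `make_thorax()` is a geometric stand-in for a
mediastinal-irradiation patient: elliptical soft-tissue torso with an
anterior surface bulge (so surface obliquity is exercised), two lung
ellipsoids at density 0.26, a bone column at 1.4, a 5-cm mediastinal
target, a neck, and a small thyroid ≥ 15 cm superior of the target so the
far-field dose regime is reachable. Densities are generic tissue-table
values. Optional Gaussian density noise (off by default, seed-controlled)
emulates CT texture.

What the phantoms do **not** emulate: real CT calibration curves, organ
shapes, elemental composition, setup uncertainty, or any particular
patient. Tests against them therefore establish qualitative findings —
isodose contours penetrate deeper through lung than through soft tissue at
matched lateral offset, far-field (≥ 15 cm) neutron equivalent dose sits in
the sub-1% band — not patient-specific absolute organ doses, which require
clinical CT, apertures and calibrated model parameters.

Default problem sizes were chosen for desk-scale iteration: the water box
at 0.25 cm spacing is 432 000 voxels and a full proton + neutron chain runs
in a few seconds; the thorax at 0.5 cm spacing is 221 000 voxels. The
compiled traversal core makes per-voxel ray tracing (one ray per voxel,
plus one per aperture pixel) the dominant but still sub-minute cost.

## Reporting conventions

* Organ statistics are voxel means with **population** SD (divide by $n$);
  the ± convention on published organ doses is usually unstated, so the
  choice is documented and switchable (`sd = "sample"`).
* Percentages normalise to the prescription at the isocenter, never to the
  maximum dose.
* DVHs are cumulative at 1%-of-prescription bin resolution, start at 100%
  volume and are non-increasing by construction.
* Combined dose is voxelwise proton (weighting factor 1) plus neutron
  equivalent dose, in Sv.
* The thorax pipeline applies a field-size correction computed against a
  circular total-field footprint (default 10 cm diameter) on the collimator
  plane; what counts as "total field" for a given nozzle is genuinely
  configuration-dependent, so the area is an explicit argument rather than
  a constant.

## Known limitations

Water-equivalent (not composition-aware) neutron attenuation; a single
virtual point source (no distributed nozzle production, no in-patient
neutrons, hence no scanned-beam validity); no buildup or scatter beyond the
attenuation term; the proton engine is a surrogate, not a commissioned
algorithm — its absolute penumbra and entrance shapes are plausible
defaults, not fits; and the packaged neutron parameters are illustrative.
Facility use requires replacing the YAML parameter set and the HU table
with calibrated ones.
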