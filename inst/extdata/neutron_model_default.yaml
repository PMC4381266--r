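# Illustrative neutron source-model parameters -- NOT a clinical calibration.
#
# The fitted parameters used in practice (p, C_i, alpha_i, sigma_i and the
# monoenergetic hd_iso table) are facility- and nozzle-specific and are not
# distributable with this package.  The values below are a physically
# plausible stand-in: fast intranuclear-cascade neutrons are forward-peaked
# (small sigma) and penetrating (moderate alpha); evaporation neutrons are
# attenuated faster; epithermal and thermal components are laterally diffuse
# (large sigma) with weak residual attenuation.  Replace every number here
# with a facility-calibrated set before any quantitative use.
#
# hd_iso is the plan-level (H/D) at isocenter in mSv/Gy.  It may be given
# directly (as here: the published value for a 140 MeV, 5-cm-modulation
# water-phantom plan with a medium scattering foil) or computed from a
# monoenergetic spectrum table -- see neutron_model_spectrum_example.yaml.
model:
  hd_iso: 3.68          # mSv/Gy at isocenter
  p: 0.9                # power-law divergence exponent
  d_iso: 33.0           # cm, virtual source (collimator) to isocenter
  dprime_iso: 7.5       # cm water-equivalent source->isocenter; usually
                        # recomputed per plan by ray tracing the anatomy
  field_size_factor: 1.0  # closed-collimator calibration condition

components:
  intranuclear-cascade: {C: 0.40, alpha: 0.060, sigma: 20.0}
  evaporation:          {C: 0.35, alpha: 0.100, sigma: 35.0}
  epithermal:           {C: 0.15, alpha: 0.020, sigma: 60.0}
  thermal:              {C: 0.10, alpha: 0.010, sigma: 100.0}
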