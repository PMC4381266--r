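# Example of supplying a monoenergetic spectrum instead of a plan-level
# hd_iso: the plan-level value is then the n-weighted sum of the bin values
# divided by the count of the maximum-energy bin.  Bin values below are
# illustrative placeholders; a calibrated table of monoenergetic isocenter
# H/D values belongs here.
model:
  p: 0.9
  d_iso: 33.0
  dprime_iso: 7.5
  field_size_factor: 1.0

components:
  intranuclear-cascade: {C: 0.40, alpha: 0.060, sigma: 20.0}
  evaporation:          {C: 0.35, alpha: 0.100, sigma: 35.0}
  epithermal:           {C: 0.15, alpha: 0.020, sigma: 60.0}
  thermal:              {C: 0.10, alpha: 0.010, sigma: 100.0}

# note the quoted "n": a bare n is YAML-1.1 shorthand for false
spectrum:
  - {energy: 100.0, "n": 0.35, hd_iso: 1.10}
  - {energy: 120.0, "n": 0.55, hd_iso: 1.60}
  - {energy: 140.0, "n": 1.00, hd_iso: 2.45}
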