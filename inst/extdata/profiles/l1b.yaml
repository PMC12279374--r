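# Deep sublamina (L1b) cohort calibration.
name: L1b
n_boutons: 171
bouton_volume: {mean: 0.58, sd: 0.17}
mito_fraction: {mean: 7.23, sd: 0.68}
preaz_area:    {mean: 0.22, sd: 0.04}
psd_ratio:     {mean: 1.00, sd: 0.10}      # 0.22/0.22
sv_diameter:   {mean: 26.73, sd: 6.63}
sv_diameter_tomo: {mean: 31.88, sd: 2.36}
pool_targets:
  rrp_p10:          {mean: 1.29, sd: 1.87}
  rrp_p20_extra:    {mean: 11.78, sd: 13.65}   # p20 13.07 minus p10
  unassigned_20_60: {mean: 76.40, sd: 30.0}    # total 3903.32 - named pools
  rp_60_200:        {mean: 535.88, sd: 321.16}
  resting_gt200:    {mean: 3277.97, sd: 1480.96}
docked: {mean: 3.42, sd: 1.34}
cleft:
  lateral: {mean: 23.34, sd: 1.70}
  central: {mean: 30.19, sd: 0.92}
coverage_probs:
  spine: [0.0869, 0.2373, 0.6757]
  shaft: [0.0854, 0.1644, 0.7502]
density_per_mm3: 5.01e8
spine_fraction: 0.79
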