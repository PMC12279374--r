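# Superficial sublamina (L1a) cohort calibration.
name: L1a
n_boutons: 190
bouton_volume: {mean: 0.41, sd: 0.21}
mito_fraction: {mean: 7.18, sd: 1.60}
preaz_area:    {mean: 0.18, sd: 0.08}
psd_ratio:     {mean: 1.17, sd: 0.10}      # 0.21/0.18
sv_diameter:   {mean: 23.33, sd: 5.27}
sv_diameter_tomo: {mean: 28.11, sd: 6.10}
pool_targets:
  rrp_p10:          {mean: 5.90, sd: 5.05}
  rrp_p20_extra:    {mean: 19.14, sd: 20.48}   # p20 25.04 minus p10
  unassigned_20_60: {mean: 28.44, sd: 15.0}    # total 2958.62 - named pools
  rp_60_200:        {mean: 390.12, sd: 286.89}
  resting_gt200:    {mean: 2515.02, sd: 1588.99}
docked: {mean: 3.71, sd: 1.38}
cleft:
  lateral: {mean: 20.17, sd: 2.85}
  central: {mean: 29.06, sd: 3.48}
coverage_probs:
  spine: [0.0869, 0.2373, 0.6757]
  shaft: [0.0854, 0.1644, 0.7502]
density_per_mm3: 5.52e8
spine_fraction: 0.81
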