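# Layer-1 (pooled sublaminae) cohort calibration.
# Morphometry, pool and docked values are the published L1 cohort
# means +- SD; the unassigned (20-60 nm) band is the remainder of the
# total pool after the named pools and carries an assumed SD.
name: L1
n_boutons: 190
bouton_volume: {mean: 0.50, sd: 0.19}      # um^3
mito_fraction: {mean: 7.21, sd: 1.10}      # percent of bouton volume
preaz_area:    {mean: 0.20, sd: 0.06}      # um^2
psd_ratio:     {mean: 1.10, sd: 0.10}      # L_PSD / L_PreAZ (0.22/0.20)
sv_diameter:   {mean: 25.03, sd: 5.67}     # nm (serial-section mode)
sv_diameter_tomo: {mean: 30.29, sd: 4.67}  # nm (tomography mode)
pool_targets:
  rrp_p10:          {mean: 3.60, sd: 4.24}
  rrp_p20_extra:    {mean: 15.45, sd: 16.70}   # p20 19.05 minus p10
  unassigned_20_60: {mean: 52.42, sd: 25.0}    # total 3430.97 - named pools
  rp_60_200:        {mean: 463.00, sd: 283.82}
  resting_gt200:    {mean: 2896.50, sd: 1435.93}
docked: {mean: 3.56, sd: 1.36}             # per AZ (tomography)
cleft:
  lateral: {mean: 21.75, sd: 2.72}         # nm
  central: {mean: 29.63, sd: 2.36}         # nm
coverage_probs:                            # both sides / one side / none
  spine: [0.0869, 0.2373, 0.6757]
  shaft: [0.0854, 0.1644, 0.7502]
density_per_mm3: 5.26e8
spine_fraction: 0.80
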