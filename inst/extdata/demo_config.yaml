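# Demo end-to-end run: simulate a paired longitudinal study, calibrate,
# score, classify BCL-2 family fold changes, correlate differential BCL2A1
# with the panel genes. All randomness flows through `seed`.
seed: 42
simulate:
  n_patients: 8
  bcl2a1_upregulated_fraction: 0.625
  fold_change_magnitude: 4
  noise_sd: 0.3
calibration:
  n_active: 10
  n_inactive: 10
  noise_sd: 0.2
foldchange:
  threshold: 2.0
  baseline_timepoint: diagnosis
  followup_timepoint: induction_2
correlate:
  anchor: BCL2A1
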