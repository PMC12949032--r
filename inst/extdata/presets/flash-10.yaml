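id: flash-10
beam:
  energy: 228.0
  sigma_iso_x: 5.6
  sigma_iso_y: 5.6
  current: 125.0
  sad_x: 298.0
  sad_y: 970.0
  pulse_rate: 1000.0
  pulse_width: 1.0e-05
  charge_per_mu: 0.1276
collimator:
  n_slits: 5.0
  slit_width: 1.0
  pitch: 2.8
  thickness: 10.0
  exit_to_surface_gap: 5.0
plan:
  field_size_cm: 3.0
  spacing_mm: 5.0
  mu_per_spot: 50.0
  pattern: A
pbs:
  threshold: 0.5
  fidelity: spot-uniform
grid:
  depths_cm:
  - 2.0
  - 4.0
  - 6.0
  - 8.0
  - 12.0
  half_extent_mm: 25.0
cal_peak_dose: 21.0
dead_time: 0.0
n_histories: 100000.0
seed: 1.0
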