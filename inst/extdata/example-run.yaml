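# Example run configuration for the ppgmc command-line interface.
# Desk-scale positive-angle sweep at two distances.
wavelengths: [520, 637, 940]
distances: [2, 5]
theta_s: [15, 25, 35, 45, 55]
theta_d: [25, 35, 45, 55]
control:
  photons_base: 2.0e6   # per-configuration budget at d_min, split over seeds
  n_seeds: 5
  seed: 1
  phase: hg             # hg | mie
  acceptance_half_angle: 15
scene:
  air_gap_thickness: 0.02
  barrier_height_above: 0
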