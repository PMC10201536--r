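# Adenine-thymine preset: full calibration of the model double-proton-transfer
# surface, the coarse-grained duplex, and the scan / path-search / steering
# protocols. All values are package calibration conventions except the
# power-law exponent, which carries the literature value for A-T.
preset: AT
surface:
  step1_reverse_base: 0.10        # eV
  step1_reverse_prefactor: 0.70   # eV / A^p
  step1_exponent: 1.894
  step2_slope: 0.50               # eV/A
  step2_onset: 0.30               # A
  spt_asymmetry_intercept: 0.55   # eV
  spt_asymmetry_slope: 0.25       # eV/A
  dpt_asymmetry_intercept: 0.45   # eV
  dpt_asymmetry_slope: 0.35       # eV/A
  sequential_penalty: 3.0         # eV
  stability_epsilon: 0.005        # eV
duplex:
  n_pairs: 14
  morse_depth_B1: 0.28            # eV
  morse_depth_B2: 0.22            # eV
  morse_width: 2.0                # 1/A
  hbond_eq_length: 2.9            # A
  stacking_k: 2.0                 # eV/A^2
  lever_arm: 4.5                  # A
  bead_mass: 150                  # amu
  temperature: 310                # K
  friction: 1.0                   # 1/ps
  timestep: 0.001                 # ps
scan:
  increment_spacing: 0.222        # A
  n_increments: 13
  ts_scan_limit: 8
  force_tolerance: 0.01           # eV/A
  max_steps: 500
mep:
  n_images: 15
  force_tolerance: 0.01
  uncertainty_tolerance: 0.02     # eV
  max_true_evaluations: 200
  seed: 1
  climbing_image: true
  spring_k: 1.0
steering:
  force: 25                       # kJ/mol/nm
  target_pair: 1
  equilibration_time: 500         # ps
  production_time: 200            # ps
  n_replicas: 8
  seed: 1
  sampling_interval: 0.01         # ps
seed: 1
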