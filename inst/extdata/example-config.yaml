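# Example lipotrack run configuration.
# Any omitted key falls back to the package default (see default_run_config()).
seed: 1

medium:
  temperature: 298.15     # K
  viscosity: 0.00089      # Pa s (water at 25 C)

acquisition:
  frame_rate: 25          # Hz
  duration: 120           # s
  mean_track_length: 50   # frames
  observed_volume: 1.0e-5 # ml

analysis:
  bin_width: 5            # nm
  smooth_window: 7        # bins (display only)
  min_steps: 10           # track-length filter
  alpha: 0.05
  min_shift: 5            # nm

population:               # 800-nm-extruded preparation
  median_diameter: 220
  geometric_sd: 1.4
  extrusion_cutoff: 800
  concentration: 3.0e+8  # particles/ml (YAML floats need a signed exponent)

binding:                  # high-curvature-preferring protein
  kind: high_curvature
  midpoint: 150
  steepness: 10
  max_prob: 0.95
  baseline_prob: 0.02

detection:
  diffraction_midpoint: 90
  diffraction_steepness: 6
  fluorescence_prob: 0.95

vesiculation:
  max_fraction: 0.8
  half_dose: 1            # uM
  hill: 1.5
  daughter_median: 70     # nm
  daughter_gsd: 1.25
  min_daughter: 20        # nm
  doses: [0, 0.5, 1, 2, 4]

simulate:
  n_particles: 6000
  n_replicates: 3
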