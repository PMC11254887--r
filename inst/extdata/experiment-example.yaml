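# Example experiment configuration for `splitgfr run-all --config ...`.
# Unspecified keys fall back to experiment_config() defaults.
seed: 7
phantom:
  n_scans: 100
  gfr_range: [20.0, 150.0]
  split_range: [0.3, 0.7]
  noise: true
  background_level: 10
  liver_prob: 0.2
training:
  input_size: 64
  base_filters: 8
  levels: 4
  epochs: 20
  batch_size: 8
  learning_rate: 0.003
  folds: 4
  augment: false
gates:
  mu: 0.153
  gates_slope: 9.8127
  gates_intercept: -6.82519
  depth_formula: tonnesen
background_roi:
  gap_px: 2
  annulus_width_px: 3
  half_angle_deg: 30
evaluation:
  abs_threshold: 5
  rel_thresholds: [10, 20]
plots: true
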