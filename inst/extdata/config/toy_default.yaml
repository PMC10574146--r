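# Desk-scale default configuration for the MTPI pipeline. Version: 2
# The shift block mirrors default_shift.yaml.
scene:
  size: 64
  blob_scale: 14
  n_source: 600
  n_target: 120
  class_mix: [0.25, 0.25, 0.25, 0.25]
shift:
  hue_shift: 20
  brightness_gain: 0.60
  saturation_gain: 0.75
  texture_contrast_gain: 1.2
  per_class_flags: [true, true, true, false]
net:
  depth: 5
  channels: [22, 14, 9, 7, 12]
  residual: false
train:
  pretrain_iterations: 900
  pretrain_conv_tol: 2.0e-4
  pretrain_conv_window: 60
  transfer_iterations: 400
  transfer_conv_tol: 1.0e-9
  batch_size: 2
  learning_rate: 0.02
  momentum: 0.9
  validation_cadence: 100
  conv_window: 40
probe:
  calibration_n: 10
  eval_n: 12
  rule: standardised
tpi:
  nlevel: 10
  form: fraction
sweep:
  tds_fractions: [0.1, 0.25, 0.5, 1, 2]
  n_seeds: 3
  conv_tol: 0.05
  max_iterations: 250
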