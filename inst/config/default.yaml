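# Default experiment configuration (see ?default_run_config for semantics).
schema_version: 1
seed: 1
n_patients: 54
sigma_rel: 0.10
mode: fast
max_fractions: 5
allow_long_courses: false
prescription_set: [5.5, 6.0, 7.0, 7.5, 8.0]
ebrt_dose: [45.0, 40.0, 40.0, 40.0]
train:
  lr_init: 5.0e-4
  plateau_factor: 0.1
  plateau_patience: 5
  plateau_warmup: 75
  batch_size: 4
  pretrain_epochs: 100
  joint_epochs: 100
  weight_decay: 1.0e-5
  adam_beta1: 0.9
  adam_beta2: 0.98
  negatives_per_plan: 4
  magnitude_low: 0.05
  magnitude_high: 0.25
  n_bins: 20
  channels: [16, 32, 32, 16]
  dense_width: 64
  dropout: 0.5
  dropout_mode: channel
  leaky_slope: 0.2
  dense_act: true
  dose_scale: 100
  rx_scale: 10
  out_scale: 10
eval:
  levels: [0.05, 0.10, 0.15, 0.20]
  k_negatives: 1
  threshold: 0.5
  sweep_from: 0.6
  sweep_to: 1.4
  sweep_by: 0.05
  audit_threshold: 0.10
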