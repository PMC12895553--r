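# Toy end-to-end configuration: 40 participants, 20 regions, 32/32 hidden.
seed: 1
synthetic:
  n_participants: 40
  n_regions: 20
model:
  n_hidden_hyper: 32
  n_hidden_main: 32
  dropout: 0.1
train:
  segment_len: 262
  batch_size: 8
  lr: 0.001
  max_epochs: 600
  early_stop_patience: 100
  val_fraction: 0.1
loss:
  lambda_action: 1
  lambda_bold: 1
split:
  train_duration_s: 196.8
intervention:
  alpha_sd: 2
  sd_threshold: 2.5
  smoothgrad_samples: 100
  noise_level: 0.1
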