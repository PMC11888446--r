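# Desk-scale demonstration experiment: a tiny rotary-embedding encoder
# trained with the calibrated curriculum schedule on a synthetic
# repertoire. Completes on one CPU in well under a minute.
seed: 7
repertoire:
  n_paired: 160
  n_unpaired_heavy: 200
  n_unpaired_light: 80
  mutation_rate: 6
  naive_fraction: 0.5
prep:
  separator_mode: unique_sep
  train_fraction: 0.96
schedule:
  kind: curriculum
  B: 0.7
  A: 0.4
  k: 15
  target_unpaired_fraction: 0.625
encoder:
  n_layers: 2
  n_heads: 4
  hidden_size: 64
  intermediate_size: 256
  pe_type: rope
train:
  total_steps: 120
  batch_size: 8
  peak_lr: 0.001
  warmup_ratio: 0.06
  lr_kind: linear
  eval_size: 16
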