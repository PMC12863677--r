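# Pipeline B: z-score normalization, intensity offsets, rarer flips.
pipeline: B
normalization:
  mode: zscore
augmentation:
  p_rescale: 0.2
  rescale_range: [0.9, 1.1]
  p_offset: 1.0
  offset_range: [-0.1, 0.1]
  p_noise: 1.0
  noise_sigma: 0.1
  p_channel_drop: 0.0
  p_flip_per_axis: 0.5
network:
  in_channels: 4
  out_channels: 3
  filters: [32, 64, 128, 256]
  groupnorm_groups: 8
  levels: 3
  pooling:
    kind: related
    window: [2, 2, 2]
    stride: 2
    weights: [0.03, 0.05, 0.07, 0.1, 0.13, 0.151, 0.214, 0.255]
training:
  epochs: 300
  batch_size: 1
  learning_rate: 1.0e-4
  folds: 5
  patch_size: [128, 128, 128]
  patches_per_case: 1
  seed: 1
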