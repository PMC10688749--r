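# Fully populated example configuration for the tlrseg CLI.
# `tlrseg.R synth --config example-config.yaml --out corpus`
# `tlrseg.R train --config example-config.yaml --data corpus --out run`

model:
  depth: 4            # encoder stages; bottleneck sits one below
  base_channels: 16   # stage-1 width (64 reproduces the canonical schedule)
  variant: lr_ccf_fc  # baseline | ccf | fc | ccf_fc | lr_ccf_fc
  rank_L: 4           # rank-1 context vectors per direction
  heads_N: 4          # channel cross-attention heads
  patch_size: 8       # stage-1 patch edge (halved per stage)
  embed_dim: 64       # shared token embedding width
  out_classes: 1      # 1 = sigmoid foreground head
  in_channels: 1
  input_size: 64      # spatial edge the model is built for
  upsample: transposed
  fc_mode: gate

train:
  epochs: 40
  batch_size: 4
  learning_rate: 0.001
  alpha: 0.5          # WCE/Dice blend
  beta: 1.0           # foreground weight in the WCE
  seed: 1
  augment: true
  cosine_decay: false
  val_every: 1

synth:
  image_size: 64
  n_images: 250
  cells_per_image: [1, 6]
  radius: [5, 14]
  overlap_prob: 0.3
  noise_sigma: 0.1
  texture: 0.15
  seed: 1
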