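# tlrseg

Cell-image segmentation with tensor low-rank channel cross-fusion skip
connections, in pure R (plus a compiled convolution kernel).

## What this is

Binary segmentation of micrograph-like cell images — bright, softly-edged,
often touching cells on a darker textured background — is usually done with
U-shaped encoder–decoder networks. The plain skip connection that copies
each encoder stage into the decoder ignores the distribution mismatch
between shallow and deep features. `tlrseg` implements a U-shaped network
whose skip path is replaced by three modules:

* **LR — tensor low-rank context.** Per encoder stage and per direction
  *d* ∈ {height, width, channel}, *L* generators apply global average
  pooling, a kernel-3 1-d convolution and a sigmoid, giving 3*L* rank-1
  context vectors in [0, 1]; each direction's vectors are projected into
  the token embedding and added to that direction's tokens.
* **CCF — channel cross-fusion.** Stage *i* is patch-embedded with patch
  edge *P*ₛ/2^(i−1) (equal token counts at every scale). With
  Q = T₍d,i₎W_Q from one stage and K, V from the four-scale concatenation,
  attention is computed over the channel axis — softmax over the key axis
  of the instance-normalised score matrix QᵀK — *N* heads are averaged, and
  a two-layer perceptron fuses the three directions:
  O_i = Σ_d [ NCA₍d,i₎ + LP(Q₍d,i₎ + NCA₍d,i₎) ].
* **FC — feature connection.** The fused encoder feature O_i and decoder
  feature D_i are global-average-pooled, passed through two linear layers,
  and the sigmoid of the sum gates O_i per channel before concatenation
  with D_i.

Training minimises `L = α·WCE + (1−α)·Dice`, where WCE is cross-entropy
with foreground weight β (class imbalance) and Dice is the soft Dice loss.
Evaluation reports Dice = 2TP/(2TP+FP+FN), IoU = TP/(TP+FP+FN), precision
and recall, all as percentages.

Five ablation variants are first-class: `baseline` (plain U-Net),
`ccf`, `fc`, `ccf_fc`, `lr_ccf_fc` (the full network). The whole engine —
forward pass, exact reverse-mode gradients, Adam — is implemented in the
package; there is no deep-learning framework underneath. A seeded synthetic
corpus generator with exact ground-truth masks makes every stage testable.

## Worked example

```r
library(tlrseg)

corpus <- generate_corpus(synthetic_spec(image_size = 64, n_images = 60, seed = 1))
cfg <- model_config(depth = 4, base_channels = 16, variant = "lr_ccf_fc")
fit <- train_model(cfg, train_config(epochs = 5, seed = 1),
                   corpus[1:50], val_pairs = corpus[51:60], verbose = TRUE)
#> epoch 1/5 loss 0.6661 val dice 44.68%
#> epoch 2/5 loss 0.4502 val dice 81.38%
#> epoch 3/5 loss 0.4107 val dice 84.71%
#> epoch 4/5 loss 0.3675 val dice 90.63%
#> epoch 5/5 loss 0.3272 val dice 92.41%
evaluate_model(fit$model, corpus[51:60])
#>     variant dice_pct miou_pct precision_pct recall_pct
#> 1 lr_ccf_fc 92.40704 85.88576      91.28905   93.55275
```

The model reaches a validation Dice of ~92% after five epochs on fifty
64×64 synthetic images: the network separates cells from background almost
pixel-perfectly, with recall slightly ahead of precision (it errs toward
including the blurred cell rim). `plot_history(fit)` draws the loss and
metric curves; `plot_prediction(image, mask, predict(fit$model, image))`
shows an example segmentation. `run_ablation()` trains all five variants on
identical data and emits the ablation table; `write_metrics_csv()` stores
any metrics table as CSV.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "tlrseg.R", package = "tlrseg")` with subcommands
`synth`, `train`, `eval`, `ablate`; a fully populated YAML configuration
example sits at `system.file("extdata", "example-config.yaml", package =
"tlrseg")`.

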