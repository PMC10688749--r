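---
title: "Low-rank channel cross-fusion skip connections: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank channel cross-fusion skip connections: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlrseg)
```

## The problem

Semantic segmentation of cell micrographs — here, binary foreground/background
masks of roundish cells whose rims blur into the background — is dominated by
U-shaped encoder–decoder networks. The encoder's job is to summarise context;
the plain skip connection that copies each encoder stage straight into the
decoder is known to be fragile: shallow encoder features and deep decoder
features live in different distributions (a "semantic gap"), and a simple
concatenation models no interaction between scales.

`tlrseg` implements a U-shaped network in which the skip path is replaced by
three cooperating modules:

1. **Tensor low-rank context (LR).** For each encoder stage, `L` generators per
   direction (height, width, channel) apply global average pooling along the
   two collapsed axes, a kernel-3 same-padded 1-d convolution, and a sigmoid,
   producing `3L` rank-1 context vectors with entries in `[0, 1]`. Rather than
   materialising the outer-product tensors these vectors imply, each direction's
   `L` vectors are summed, projected to the token embedding width and added to
   that direction's token sequence — an `O(L (H + W + C))` representation of
   high-rank context.
2. **Channel cross-fusion (CCF).** Stage `i` is cut into square patches of edge
   `Ps / 2^(i-1)`, so all stages yield the same token count; each flattened
   patch is linearly embedded into a shared width `E`. Queries come from one
   stage, keys and values from the concatenation of all stages, and attention
   is computed over the *channel* axis: the `E x E` score matrix `t(Q) K` is
   instance-normalised, row-softmaxed over the key axis, and applied to the
   values. `N` heads are averaged, and a two-layer GELU perceptron `LP` fuses
   the three direction branches per stage:
   `O_i = sum_d [ NCA_{d,i} + LP(Q_{d,i} + NCA_{d,i}) ]`,
   after which tokens are projected back to patches and reassembled.
3. **Feature connection (FC).** Before decoding at stage `i`, the fused
   encoder feature `O_i` (aligned by upsampling + 3x3 convolution) and the
   decoder feature `D_i` are each global-average-pooled per channel and passed
   through their own linear layer; the sigmoid of the summed outputs is a
   per-channel gate `g` in `(0, 1)`, and the decoder consumes the channel
   concatenation of `g * O_i` and `D_i`.

The training loss blends weighted cross-entropy and soft Dice loss,
`L = alpha * WCE + (1 - alpha) * Dice`, with WCE carrying a foreground weight
`beta` because cell foreground is a small fraction of the pixels.

## Design choices where the design was open

Several pieces of the architecture admit more than one faithful reading; the
package fixes them as follows and exposes the alternatives where reasonable.

* **Key/value folding in the cross attention.** The four-scale concatenation
  stacks equal-length token blocks whose tokens correspond spatially (the
  patch edges are chosen to force equal counts). With every projection an
  `E x E` matrix and channel-wise scores of shape `E x E`, the key and value
  sequences are folded to per-token means over their stage blocks before the
  score contraction. This keeps every stated shape exact — scores `E x E`,
  attention rows summing to 1, output in the query's token layout — while the
  cross-scale information enters through the folded keys/values.
* **Score normalisation.** The normalisation inside the attention is
  whole-matrix (instance) standardisation of the scores; the activation is a
  row softmax. No `1/sqrt(d_k)` scaling is applied; the instance
  normalisation already fixes the score scale.
* **Heads.** The `N` averaged heads carry distinct `W_Q/W_K/W_V` triples per
  direction; the `Q` entering the perceptron fusion is the head average,
  consistent with the head-averaged attention output.
* **Gate recombination.** The feature-connection output is read as an
  SE-style channel gate on `O_i` followed by concatenation with `D_i`
  (`fc_mode = "gate"`); element-wise addition of the gate
  (`fc_mode = "add"`) is kept as a selectable alternative for comparison.
* **Backbone details.** Convolutions are 3x3 with same padding (skips align
  without cropping), each followed by batch normalisation and ReLU; decoder
  upsampling is a 2x2 transposed convolution by default with bilinear + 1x1
  convolution as an option; the output head is a sigmoid for one class and a
  softmax for two or more. He-uniform initialisation throughout, seeded.
* **Defaults left unstated by the design.** `depth = 4`, `base_channels = 64`
  (the canonical schedule; 16 is the desk-scale setting used in the examples
  and tests), `L = 4`, `N = 4`, `Ps = 8`, `embed_dim = 64`, perceptron hidden
  width `4 * embed_dim`, `alpha = 0.5`, `beta = 1`, `epsilon = 1e-6`.

Because the low-rank projections are sized by the height/width profiles, a
model with the LR module is built for a fixed `input_size`; the other
variants accept any admissible size.

## The engine

No deep-learning framework is used: the forward pass and the exact
reverse-mode gradients of every block are implemented directly on matrix
algebra, with the 3x3 convolution (im2col + GEMM) and GELU in compiled code.
Every gradient is validated in the test suite against central finite
differences on small models of each variant; the optimiser is a standard
Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) at a constant learning
rate (cosine decay is available behind a flag, off by default). Training is
deterministic for a fixed seed — there are no nondeterministic kernels — so
strict reproducibility holds without a separate mode.

Numerical conventions worth noting: probabilities are clamped to
`[epsilon, 1 - epsilon]` before logarithms; the soft Dice loss uses the
`epsilon`-smoothed ratio; `predict_mask` sends ties at the threshold to
foreground; Dice and IoU of two empty masks are defined as 100%, while
precision/recall with empty denominators are `NA` and excluded from
macro averages; batch normalisation keeps running statistics (momentum 0.1)
used at inference.

## What the synthetic corpus emulates — and what it does not

The generator (`synthetic_spec()`, `generate_corpus()`) emulates micrographs
of reproductive-type cells: bright elliptical cells (radius 5–14 px at the
default 64 px frame, aspect 0.7–1, random orientation) with an intensity
falloff toward a softly rasterised rim — mimicking out-of-focus cytoplasm
edges, so the cell/background boundary is deliberately not crisp — on a
darker low-frequency textured background, with additive Gaussian noise and a
30% chance that each later cell is placed touching or overlapping an earlier
one. Masks are the exact unions of the generating ellipses. Foreground
averages well under 35% of pixels, so the class imbalance that motivates the
weighted cross-entropy is present. All randomness derives from one seed;
identical seeds give bit-identical corpora.

The generator does **not** model time-lapse sequences, instance labels,
illumination drift, debris, or the full texture statistics of real
micrographs. Passing the end-to-end checks on this corpus demonstrates that
the architecture, gradients, losses and training loop are correct and that
the full variant can learn the task; it does not certify clinical-grade
accuracy on real reproductive-cell images, which are not publicly available.

## Problem sizes used in the checks

The test suite and the acceptance script run at deliberately small scales
chosen as a desk-scale study: gradient checks on depth-2 models at 16 px;
an overfit check (depth 3, base 16, one 64 px image, 200 Adam steps,
no augmentation) that must exceed 99% training Dice — the standard oracle
for correct gradient flow; and a scaled end-to-end run (200 training / 25
validation images at 64 px, full `lr_ccf_fc` variant at base 16, 15 epochs,
batch 4, learning rate 0.001) that must reach at least 90% validation Dice.
The ablation contrast reported by the acceptance script (full variant versus
baseline, mean validation Dice over 3 seeds) runs at a further reduced scale
(32 px, depth 3, base 8, 40/8 images, 5 epochs); at these sizes individual
seeds are noisy, which is why the contrast is reported as a mean and read as
an indication, not a measurement.

## Known limitations

* CPU-only and single-threaded beyond BLAS; the engine is sized for
  desk-scale experiments, not production training runs.
* Square, power-of-two inputs; no 3-D volumes; binary or few-class outputs
  only (no multi-class cell typing).
* The LR variant is input-size-specific (see above).
* Metrics are pixel-level only — no boundary-distance metrics.
* The folded key/value reading of the cross attention is one defensible
  interpretation of the channel cross-fusion design; others (for example
  block-structured projections over a channel-axis concatenation) would
  change parameter shapes but not the module's interface.

## A worked example

```{r example, eval = FALSE}
library(tlrseg)

corpus <- generate_corpus(synthetic_spec(image_size = 64, n_images = 60, seed = 1))
cfg <- model_config(depth = 4, base_channels = 16, variant = "lr_ccf_fc")
fit <- train_model(cfg, train_config(epochs = 5, seed = 1),
                   corpus[1:50], val_pairs = corpus[51:60], verbose = TRUE)
evaluate_model(fit$model, corpus[51:60])
plot_history(fit)
plot_prediction(corpus[[51]]$image, corpus[[51]]$mask,
                predict(fit$model, corpus[[51]]$image))
```
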