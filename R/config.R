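#' Model architecture configuration
#'
#' Describes a U-shaped encoder-decoder segmentation network whose skip
#' connections can be replaced, per `variant`, by a tensor low-rank context
#' module (LR), a channel cross-fusion attention module (CCF) and a
#' feature-connection gating module (FC).
#'
#' @param depth Number of encoder stages (the bottleneck sits one stage
#'   below stage `depth`). Default 4, the canonical U-Net schedule.
#' @param base_channels Channel width of stage 1; stage `i` has
#'   `base_channels * 2^(i-1)` channels. Default 64; 16 is a practical
#'   desk-scale setting.
#' @param variant One of `"baseline"` (plain U-Net skip concatenation),
#'   `"ccf"`, `"fc"`, `"ccf_fc"`, `"lr_ccf_fc"` (the full network).
#' @param rank_L Number of rank-1 context vectors generated per direction
#'   (height, width, channel) by the low-rank module; `3 * rank_L` vectors
#'   per encoder stage in total.
#' @param heads_N Number of channel cross-attention heads averaged in the
#'   cross-fusion module.
#' @param patch_size Patch edge used to tokenise stage 1; stage `i` uses
#'   `patch_size / 2^(i-1)` so every stage yields the same token count.
#' @param out_classes Number of output classes. 1 (default) uses a sigmoid
#'   foreground-probability head; `>= 2` uses a per-pixel softmax.
#' @param embed_dim Shared token embedding width of the cross-fusion module.
#' @param in_channels Image channels (1 for grayscale, 3 for RGB).
#' @param input_size Spatial edge the model is built for (square inputs);
#'   the low-rank projections are sized from it.
#' @param upsample Decoder upsampling: `"transposed"` (2x2 transposed
#'   convolution, default) or `"bilinear"` (bilinear + 1x1 convolution).
#' @param fc_mode How the feature-connection gate recombines the fused
#'   encoder feature: `"gate"` (sigmoid channel gate on O, then concat with
#'   D, default) or `"add"` (gate added to O before concat).
#'
#' @return An object of class `tlr_model_config`.
#' @export
model_config <- function(depth = 4L, base_channels = 64L,
                         variant = c("baseline", "ccf", "fc", "ccf_fc", "lr_ccf_fc"),
                         rank_L = 4L, heads_N = 4L, patch_size = 8L,
                         out_classes = 1L, embed_dim = 64L, in_channels = 1L,
                         input_size = 64L,
                         upsample = c("transposed", "bilinear"),
                         fc_mode = c("gate", "add")) {
  variant <- match.arg(variant)
  upsample <- match.arg(upsample)
  fc_mode <- match.arg(fc_mode)
  depth <- as.integer(depth)
  assert_that(depth >= 1L, "depth must be >= 1")
  assert_that(base_channels >= 1L, "base_channels must be >= 1")
  assert_that(rank_L >= 1L, "rank_L must be >= 1")
  assert_that(heads_N >= 1L, "heads_N must be >= 1")
  assert_that(out_classes >= 1L, "out_classes must be >= 1")
  assert_that(patch_size %% 2L^(depth - 1L) == 0L,
              "patch_size (%d) must be divisible by 2^(depth-1) = %d so all stages yield identical token counts",
              patch_size, 2L^(depth - 1L))
  assert_that(input_size %% 2L^depth == 0L,
              "input_size (%d) must be divisible by 2^depth = %d",
              input_size, 2L^depth)
  assert_that(input_size %% patch_size == 0L,
              "input_size (%d) must be divisible by patch_size (%d)",
              input_size, patch_size)
  structure(list(
    depth = depth, base_channels = as.integer(base_channels),
    variant = variant, rank_L = as.integer(rank_L),
    heads_N = as.integer(heads_N), patch_size = as.integer(patch_size),
    out_classes = as.integer(out_classes), embed_dim = as.integer(embed_dim),
    in_channels = as.integer(in_channels), input_size = as.integer(input_size),
    upsample = upsample, fc_mode = fc_mode
  ), class = "tlr_model_config")
}

cfg_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)
cfg_bott_channels <- function(cfg) cfg$base_channels * 2L^cfg$depth
cfg_has_ccf <- function(cfg) cfg$variant %in% c("ccf", "ccf_fc", "lr_ccf_fc")
cfg_has_fc <- function(cfg) cfg$variant %in% c("fc", "ccf_fc", "lr_ccf_fc")
cfg_has_lr <- function(cfg) cfg$variant == "lr_ccf_fc"
cfg_stage_sizes <- function(cfg, H = cfg$input_size) H %/% 2L^(seq_len(cfg$depth) - 1L)
cfg_patch_sizes <- function(cfg) cfg$patch_size %/% 2L^(seq_len(cfg$depth) - 1L)
cfg_n_tokens <- function(cfg, H = cfg$input_size) (H %/% cfg$patch_size)^2L

#' @export
print.tlr_model_config <- function(x, ...) {
  cat(sprintf("<tlr_model_config> variant=%s depth=%d base=%d embed=%d heads=%d L=%d Ps=%d input=%d\n",
              x$variant, x$depth, x$base_channels, x$embed_dim, x$heads_N,
              x$rank_L, x$patch_size, x$input_size))
  invisible(x)
}

#' Loss configuration
#'
#' Parameters of the composite training loss
#' `L = alpha * WCE + (1 - alpha) * DiceLoss`.
#'
#' @param alpha Blend weight in `[0, 1]` between weighted cross-entropy
#'   (`alpha = 1`) and Dice loss (`alpha = 0`).
#' @param beta Positive-class weight of the weighted cross-entropy; values
#'   above 1 up-weight foreground pixels to counter class imbalance.
#' @param epsilon Smoothing constant of the soft Dice loss and probability
#'   clamp for the logarithms.
#'
#' @return An object of class `tlr_loss_config`.
#' @export
loss_config <- function(alpha = 0.5, beta = 1, epsilon = 1e-6) {
  assert_that(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  assert_that(beta > 0, "beta must be positive")
  assert_that(epsilon > 0, "epsilon must be positive")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "tlr_loss_config")
}

#' Training configuration
#'
#' @param epochs Number of passes over the training split (default 40).
#' @param batch_size Mini-batch size (default 4).
#' @param learning_rate Adam learning rate (default 0.001), held constant
#'   unless `cosine_decay` is enabled.
#' @param alpha,beta Loss blend weight and foreground weight; see
#'   [loss_config()].
#' @param seed Master seed for shuffling, augmentation and weight
#'   initialisation.
#' @param augment Apply random horizontal/vertical flips to each training
#'   batch (the only augmentation used).
#' @param cosine_decay Optional cosine learning-rate decay to zero over
#'   `epochs`; off by default (constant rate).
#' @param val_every Validate every this many epochs.
#'
#' @return An object of class `tlr_train_config`.
#' @export
train_config <- function(epochs = 40L, batch_size = 4L, learning_rate = 1e-3,
                         alpha = 0.5, beta = 1, seed = 1L, augment = TRUE,
                         cosine_decay = FALSE, val_every = 1L) {
  assert_that(epochs >= 1L, "epochs must be >= 1")
  assert_that(batch_size >= 1L, "batch_size must be >= 1")
  assert_that(learning_rate > 0, "learning_rate must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, alpha = alpha, beta = beta,
                 seed = as.integer(seed), augment = isTRUE(augment),
                 cosine_decay = isTRUE(cosine_decay),
                 val_every = as.integer(val_every)),
            class = "tlr_train_config")
}

#' Ablation variant labels
#'
#' The five architecture variants of the ablation design, in canonical
#' order, with the display labels used in metrics tables.
#'
#' @return Named character vector mapping variant ids to display labels.
#' @export
ablation_variants <- function() {
  c(baseline = "Baseline(U-Net)",
    ccf = "Baseline+CCF",
    fc = "Baseline+FC",
    ccf_fc = "Baseline+CCF+FC",
    lr_ccf_fc = "Baseline+LR+CCF+FC")
}
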