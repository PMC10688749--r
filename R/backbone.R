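# User-facing backbone operations on single images.  Images and feature
# maps are (C, H, W) arrays; a plain H x W matrix is treated as 1-channel.

as_feature <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  assert_that(length(dim(x)) == 3L, "a feature map must be a (channel, height, width) array")
  x
}

#' Run the encoder
#'
#' Applies the stage-wise double-convolution encoder to one image and
#' returns every stage output plus the bottleneck. Stage `i` has
#' `base_channels * 2^(i-1)` channels at `1/2^(i-1)` of the input
#' resolution; the bottleneck sits one stage further down. Batch-norm uses
#' its running statistics (inference mode).
#'
#' @param image `(C, H, W)` array or `H x W` matrix (square spatial grid,
#'   side divisible by `2^depth` and, for attention variants, by
#'   `patch_size`).
#' @param model A `tlr_model` from [build_model()].
#' @return List with `stages` (list of `(C_i, H_i, W_i)` arrays) and
#'   `bottleneck`.
#' @export
encode <- function(image, model) {
  stopifnot(inherits(model, "tlr_model"))
  a <- as_feature(image)
  H <- dim(a)[2L]
  assert_that(dim(a)[3L] == H, "square inputs required (got %dx%d)", H, dim(a)[3L])
  assert_that(dim(a)[1L] == model$config$in_channels,
              "image has %d channels but the model expects %d",
              dim(a)[1L], model$config$in_channels)
  check_input_size(model$config, H)
  cfg <- model$config
  stenv <- new.env(parent = emptyenv())
  stenv$s <- model$state
  sizes <- cfg_stage_sizes(cfg, H)
  cur <- matrix(a, dim(a)[1L])
  stages <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    dc <- dconv_fwd(model$params, stenv, sprintf("enc.s%d", i), cur, sizes[i], 1L, FALSE)
    stages[[i]] <- as_chw(dc$y, sizes[i], sizes[i])
    cur <- maxpool2_fwd(dc$y, sizes[i], sizes[i], 1L)$y
  }
  bt <- dconv_fwd(model$params, stenv, "enc.bott", cur, sizes[cfg$depth] %/% 2L, 1L, FALSE)
  hb <- sizes[cfg$depth] %/% 2L
  list(stages = stages, bottleneck = as_chw(bt$y, hb, hb))
}

#' Run the decoder on fused skips
#'
#' Upsamples from the bottleneck and concatenates the supplied fused skip
#' feature at each stage (this is the plain-concatenation decoding path;
#' the full forward pass routes skips through the configured fusion
#' modules instead). Returns per-pixel class scores and the probability
#' map after the output head (sigmoid for one class, softmax otherwise).
#'
#' @param model A `tlr_model`.
#' @param bottleneck `(C, H, W)` bottleneck array as produced by [encode()].
#' @param fused_skips List of per-stage `(C_i, H_i, W_i)` arrays, stage 1
#'   first, spatially matching the decoder stages.
#' @return List with `scores` and `prob`, both `(out_classes, H, W)`.
#' @export
decode <- function(model, bottleneck, fused_skips) {
  stopifnot(inherits(model, "tlr_model"))
  cfg <- model$config
  d <- cfg$depth
  assert_that(length(fused_skips) == d, "expected %d fused skips, got %d",
              d, length(fused_skips))
  bt <- as_feature(bottleneck)
  ch <- cfg_channels(cfg)
  hb <- dim(bt)[2L]
  stenv <- new.env(parent = emptyenv())
  stenv$s <- model$state
  p <- model$params
  cur <- matrix(bt, dim(bt)[1L])
  curH <- hb
  for (i in rev(seq_len(d))) {
    if (cfg$upsample == "transposed") {
      up <- upconv2_fwd(cur, p[[sprintf("dec.s%d.up.W", i)]],
                        p[[sprintf("dec.s%d.up.b", i)]], curH, curH, 1L)$y
    } else {
      bl <- bilinear2_fwd(cur, curH, curH, 1L)$y
      up <- conv1x1_fwd(bl, p[[sprintf("dec.s%d.up.W", i)]],
                        p[[sprintf("dec.s%d.up.b", i)]])$y
    }
    curH <- 2L * curH
    sk <- as_feature(fused_skips[[i]])
    if (dim(sk)[2L] != curH || dim(sk)[3L] != curH) {
      stop_dim("fused skip for stage %d is %dx%d but the decoder stage is %dx%d",
               i, dim(sk)[2L], dim(sk)[3L], curH, curH)
    }
    if (dim(sk)[1L] != ch[i]) {
      stop_dim("fused skip for stage %d has %d channels, expected %d",
               i, dim(sk)[1L], ch[i])
    }
    skip <- rbind(matrix(sk, dim(sk)[1L]), up)
    cur <- dconv_fwd(p, stenv, sprintf("dec.s%d", i), skip, curH, 1L, FALSE)$y
  }
  scores <- p[["head.W"]] %*% cur + p[["head.b"]]
  list(scores = as_chw(scores, curH, curH),
       prob = as_chw(prob_head(scores, cfg$out_classes), curH, curH))
}

#' Threshold a probability map into a binary mask
#'
#' Pixels with probability greater than or equal to `threshold` become
#' foreground (ties map to foreground).
#'
#' @param prob Numeric array with values in `[0, 1]`.
#' @param threshold Decision threshold in `(0, 1)`.
#' @return Integer array of 0/1 with the shape of `prob`.
#' @export
predict_mask <- function(prob, threshold = 0.5) {
  if (any(prob < 0 | prob > 1)) {
    stop("prob must contain probabilities in [0, 1]", call. = FALSE)
  }
  assert_that(threshold > 0 && threshold < 1, "threshold must lie in (0, 1)")
  m <- (prob >= threshold) * 1L
  if (!is.null(dim(prob))) dim(m) <- dim(prob)
  m
}

#' Predict a segmentation for one image
#'
#' Full forward pass (inference mode) through the configured variant.
#'
#' @param object A `tlr_model`.
#' @param image `(C, H, W)` array or `H x W` matrix.
#' @param type `"prob"` for the probability map, `"mask"` for the
#'   thresholded binary mask.
#' @param threshold Threshold used when `type = "mask"`.
#' @param ... Unused.
#' @return `H x W` matrix (single class) or `(out_classes, H, W)` array.
#' @export
predict.tlr_model <- function(object, image, type = c("prob", "mask"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  a <- as_feature(image)
  H <- dim(a)[2L]
  fwd <- net_forward(object, matrix(a, dim(a)[1L]), 1L, H, training = FALSE)
  pr <- if (object$config$out_classes == 1L) {
    matrix(fwd$prob, H, H)
  } else {
    as_chw(fwd$prob, H, H)
  }
  if (type == "prob") pr else predict_mask(pr, threshold)
}
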