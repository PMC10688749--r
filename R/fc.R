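# Feature-connection module: single-sample operations.

#' Align a fused encoder feature to a decoder feature
#'
#' Upsamples by nearest neighbour to the target's spatial grid (the scale
#' factor must be a positive integer) and applies a 3x3 same-padded
#' convolution mapping to the target's channel count.
#'
#' @param O `(C, H, W)` array or `H x W` matrix to align.
#' @param target `(C_t, H_t, W_t)` array giving the target geometry.
#' @param params List with `W` (`C_t x C x 9` array) and `b` (`C_t`).
#' @return `(C_t, H_t, W_t)` array.
#' @export
fc_align <- function(O, target, params) {
  a <- as_feature(O)
  tg <- as_feature(target)
  H <- dim(a)[2L]; Ht <- dim(tg)[2L]
  assert_that(dim(a)[3L] == H && dim(tg)[3L] == Ht, "square feature maps required")
  if (Ht %% H != 0L) {
    stop_dim("target size %d is not an integer multiple of the input size %d", Ht, H)
  }
  f <- Ht %/% H
  up <- nn_upsample_fwd(matrix(a, dim(a)[1L]), H, H, 1L, f)$y
  y <- conv3_fwd(up, params$W, params$b, Ht, Ht, 1L)$y
  as_chw(y, Ht, Ht)
}

#' Gated connection of encoder and decoder features
#'
#' Global-average-pools the aligned encoder feature `O` and the decoder
#' feature `D` per channel, passes each through its own linear layer, adds
#' the two outputs and squashes them with a sigmoid into a per-channel
#' gate `g` in `(0, 1)`. With `mode = "gate"` (default) the output is the
#' channel concatenation of `g * O` and `D`; with `mode = "add"` the gate
#' is added to `O` instead of multiplying it.
#'
#' @param O,D `(C, H, W)` arrays of identical shape.
#' @param params List with `W1`, `b1`, `W2`, `b2`: two `C x C` linear
#'   layers (O-side and D-side).
#' @param mode `"gate"` or `"add"`.
#' @return List with `out` (`(2C, H, W)` array) and `gate` (length-`C`
#'   vector in `(0, 1)`).
#' @export
fc_connect <- function(O, D, params, mode = c("gate", "add")) {
  mode <- match.arg(mode)
  a <- as_feature(O)
  dd <- as_feature(D)
  if (!identical(dim(a), dim(dd))) {
    stop_dim("O (%s) and D (%s) must be aligned to identical shapes",
             paste(dim(a), collapse = "x"), paste(dim(dd), collapse = "x"))
  }
  C <- dim(a)[1L]; H <- dim(a)[2L]
  Om <- matrix(a, C); Dm <- matrix(dd, C)
  gO <- rowMeans(Om)
  gD <- rowMeans(Dm)
  g <- as.vector(sigmoid(params$W1 %*% gO + params$b1 + params$W2 %*% gD + params$b2))
  top <- if (mode == "gate") Om * g else Om + g
  list(out = as_chw(rbind(top, Dm), H, dim(a)[3L]), gate = g)
}
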