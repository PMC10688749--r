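# Channel cross-fusion module: single-sample operations on token
# sequences.  A token sequence is an n_tokens x embed_dim matrix; the four
# encoder scales use patch edges Ps, Ps/2, Ps/4, Ps/8 so their token
# counts coincide and tokens correspond spatially across scales.

#' Patch-embed one encoder stage into tokens
#'
#' Splits the stage feature into square patches (edge
#' `patch_size / 2^(stage_index - 1)`), flattens each patch and applies a
#' learned linear projection; optionally adds a per-direction context
#' embedding (from the low-rank module) to every token.
#'
#' @param stage_feature `(C, H, W)` array or `H x W` matrix.
#' @param stage_index Stage number `i >= 1`; halves the patch edge per
#'   stage so all stages yield `(H_1 / patch_size)^2` tokens.
#' @param params List with `W` (`embed_dim x (C * P^2)`) and `b`
#'   (`embed_dim`).
#' @param patch_size Stage-1 patch edge `Ps`.
#' @param context Optional length-`embed_dim` vector added to every token.
#' @return `n_tokens x embed_dim` token matrix.
#' @export
embed_patches <- function(stage_feature, stage_index, params, patch_size = 8L,
                          context = NULL) {
  a <- as_feature(stage_feature)
  H <- dim(a)[2L]
  assert_that(dim(a)[3L] == H, "square stage features required")
  P <- patch_size %/% 2L^(stage_index - 1L)
  assert_that(P >= 1L, "patch size vanishes at stage %d (Ps=%d)", stage_index, patch_size)
  if (H %% P != 0L) {
    stop_dim("stage size %d is not divisible by its patch size %d", H, P)
  }
  Pm <- patch_gather(matrix(a, dim(a)[1L]), H, 1L, P)
  tok <- params$W %*% Pm + params$b
  if (!is.null(context)) tok <- tok + context
  t(tok)
}

#' Concatenate the per-stage token sequences
#'
#' Stacks the token sequences of the four scales along the token axis in
#' stage order, producing the multi-scale sequence consumed as the
#' key/value source of the cross attention.
#'
#' @param tokens List of `n x embed_dim` token matrices (stage order).
#' @return `(sum n) x embed_dim` matrix.
#' @export
concat_scales <- function(tokens) {
  ed <- unique(vapply(tokens, ncol, integer(1)))
  if (length(ed) != 1L) {
    stop_dim("token sequences have mismatched embedding widths (%s)",
             paste(vapply(tokens, ncol, integer(1)), collapse = ", "))
  }
  do.call(rbind, tokens)
}

#' Channel-wise cross attention
#'
#' Queries come from one stage's tokens, keys and values from the
#' multi-scale concatenation: `Q = T_di W_Q`, `K = T_dSum W_K`,
#' `V = T_dSum W_V`. Because the concatenation stacks equal-length stage
#' blocks whose tokens correspond spatially, K and V are folded to
#' per-token means over the stage blocks; the score matrix `t(Q) Kbar`
#' (embed_dim x embed_dim, attention over the channel axis) is
#' instance-normalised and row-softmaxed over the key axis, and
#' `CA = Vbar t(weights)` returns to the query token layout.
#'
#' @param T_di `n x embed_dim` query-side tokens.
#' @param T_dSum `(k*n) x embed_dim` concatenated key/value tokens (`k`
#'   equal stage blocks).
#' @param params List with square matrices `W_Q`, `W_K`, `W_V`
#'   (`embed_dim x embed_dim`).
#' @return List with `ca` (`n x embed_dim`) and `weights`
#'   (`embed_dim x embed_dim`, rows summing to 1).
#' @export
cross_attention <- function(T_di, T_dSum, params) {
  E <- ncol(T_di)
  if (ncol(T_dSum) != E) {
    stop_dim("T_dSum embedding width %d does not match T_di width %d", ncol(T_dSum), E)
  }
  for (nm in c("W_Q", "W_K", "W_V")) {
    if (!all(dim(params[[nm]]) == c(E, E))) {
      stop_dim("%s must be %dx%d", nm, E, E)
    }
  }
  n <- nrow(T_di)
  if (nrow(T_dSum) %% n != 0L) {
    stop_dim("T_dSum token count %d is not a multiple of T_di token count %d",
             nrow(T_dSum), n)
  }
  k <- nrow(T_dSum) %/% n
  Q <- T_di %*% params$W_Q
  K <- T_dSum %*% params$W_K
  V <- T_dSum %*% params$W_V
  fold <- function(M) {
    acc <- 0
    for (j in seq_len(k)) acc <- acc + M[((j - 1L) * n + 1L):(j * n), , drop = FALSE]
    acc / k
  }
  Kb <- fold(K)
  Vb <- fold(V)
  S <- crossprod(Q, Kb)
  A <- softmax_rows(instnorm_fwd(S)$y)
  list(ca = Vb %*% t(A), weights = A)
}

#' Average attention heads
#'
#' Elementwise mean of the `N` channel cross-attention head outputs.
#'
#' @param heads Non-empty list of equally shaped matrices.
#' @param N Number of heads; defaults to `length(heads)`.
#' @return Matrix of the same shape.
#' @export
multi_head_average <- function(heads, N = length(heads)) {
  if (length(heads) == 0L) stop("head list must be non-empty", call. = FALSE)
  assert_that(N == length(heads), "N (%d) must equal the number of heads (%d)",
              N, length(heads))
  d1 <- dim(heads[[1L]])
  for (h in heads) {
    if (!identical(dim(h), d1)) stop_dim("attention heads have mismatched shapes")
  }
  Reduce(`+`, heads) / N
}

#' Perceptron fusion of the three direction branches
#'
#' Computes `O = sum_d [ NCA_d + LP(Q_d + NCA_d) ]` over the height, width
#' and channel branches, where `LP` is a two-layer perceptron with GELU
#' nonlinearity, and optionally un-patches the fused tokens back to a
#' spatial feature map.
#'
#' @param Q_parts,NCA_parts Named or ordered lists of three
#'   `n x embed_dim` matrices (directions height, width, channel).
#' @param lp_params List with `W1` (`hidden x embed_dim`), `b1`, `W2`
#'   (`embed_dim x hidden`), `b2`.
#' @param unembed Optional list with `W` (`(C*P^2) x embed_dim`), `b`,
#'   `channels`, `size`, `patch`; when supplied the fused tokens are
#'   projected back to patches and reassembled into a `(C, size, size)`
#'   array.
#' @return `n x embed_dim` fused token matrix, or a `(C, size, size)`
#'   array when `unembed` is given.
#' @export
fuse_stage <- function(Q_parts, NCA_parts, lp_params, unembed = NULL) {
  assert_that(length(Q_parts) == 3L && length(NCA_parts) == 3L,
              "exactly three direction branches are required")
  d1 <- dim(NCA_parts[[1L]])
  for (m in c(Q_parts, NCA_parts)) {
    if (!identical(dim(m), d1)) stop_dim("direction branches have mismatched shapes")
  }
  lp <- function(X) {
    h <- gelu_fwd(lp_params$W1 %*% X + lp_params$b1)$y
    lp_params$W2 %*% h + lp_params$b2
  }
  acc <- 0
  for (j in 1:3) {
    nca <- t(NCA_parts[[j]])   # embed x n
    q <- t(Q_parts[[j]])
    acc <- acc + nca + lp(q + nca)
  }
  if (is.null(unembed)) return(t(acc))
  R <- unembed$W %*% acc + unembed$b
  as_chw(patch_scatter(R, unembed$size, 1L, unembed$patch, unembed$channels),
         unembed$size, unembed$size)
}
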