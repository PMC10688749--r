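# Independent brute-force oracles and tiny fixtures.  Everything here is
# written as plainly as possible (nested loops, no shared kernels with the
# package) so it can serve as a reference for the vectorised implementation.

# 3x3 same-padded cross-correlation, looped pixel by pixel
bf_conv3 <- function(x, W, b) {
  # x: (Cin, H, W) array; W: (Cout, Cin, 9) with k indexing (dx, dy) in
  # column-major -1:1 order; b: length Cout
  d <- dim(x); H <- d[2L]; Wd <- d[3L]
  Cout <- dim(W)[1L]
  y <- array(0, c(Cout, H, Wd))
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  for (co in seq_len(Cout)) for (yy in seq_len(H)) for (xx in seq_len(Wd)) {
    acc <- b[co]
    for (k in 1:9) {
      y2 <- yy + offs$dy[k]; x2 <- xx + offs$dx[k]
      if (y2 >= 1 && y2 <= H && x2 >= 1 && x2 <= Wd) {
        for (ci in seq_len(d[1L])) acc <- acc + W[co, ci, k] * x[ci, y2, x2]
      }
    }
    y[co, yy, xx] <- acc
  }
  y
}

# direction pooling by explicit iteration over the collapsed axes
bf_direction_pool <- function(x, direction) {
  d <- dim(x)
  if (direction == "height") {
    vapply(seq_len(d[2L]), function(y) mean(x[, y, ]), numeric(1))
  } else if (direction == "width") {
    vapply(seq_len(d[3L]), function(w) mean(x[, , w]), numeric(1))
  } else {
    vapply(seq_len(d[1L]), function(c) mean(x[c, , ]), numeric(1))
  }
}

# kernel-3 same-padded 1-d cross-correlation + sigmoid, index by index
bf_context_vector <- function(v, k, b) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- b
    if (i > 1) s <- s + k[1] * v[i - 1]
    s <- s + k[2] * v[i]
    if (i < n) s <- s + k[3] * v[i + 1]
    out[i] <- 1 / (1 + exp(-s))
  }
  out
}

# explicit channel cross-attention: scores, whole-matrix normalisation,
# row softmax, value mixing -- about ten lines, no shared code
bf_cross_attention <- function(T_di, T_dSum, W_Q, W_K, W_V) {
  n <- nrow(T_di)
  k <- nrow(T_dSum) / n
  Q <- T_di %*% W_Q
  K <- T_dSum %*% W_K
  V <- T_dSum %*% W_V
  Kb <- matrix(0, n, ncol(K)); Vb <- Kb
  for (j in seq_len(k)) {
    Kb <- Kb + K[((j - 1) * n + 1):(j * n), , drop = FALSE] / k
    Vb <- Vb + V[((j - 1) * n + 1):(j * n), , drop = FALSE] / k
  }
  S <- t(Q) %*% Kb
  Z <- (S - mean(S)) / sqrt(mean((S - mean(S))^2) + 1e-5)
  A <- matrix(0, nrow(Z), ncol(Z))
  for (r in seq_len(nrow(Z))) A[r, ] <- exp(Z[r, ] - max(Z[r, ])) / sum(exp(Z[r, ] - max(Z[r, ])))
  list(ca = Vb %*% t(A), weights = A)
}

# flood-fill connected components (4-neighbourhood) on a binary matrix
bf_n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  ncomp <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      ncomp <- ncomp + 1L
      stack <- list(c(i, j))
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask)) next
        if (mask[p[1], p[2]] != 1 || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- ncomp
        stack <- c(stack, list(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                               c(p[1], p[2] - 1), c(p[1], p[2] + 1)))
      }
    }
  }
  ncomp
}

# a tiny architecture used across tests (fast to build and run)
tiny_config <- function(variant = "lr_ccf_fc", ...) {
  model_config(depth = 2L, base_channels = 2L, variant = variant, rank_L = 2L,
               heads_N = 2L, patch_size = 8L, embed_dim = 8L, input_size = 16L, ...)
}

rand_feature <- function(C, H, W, seed = 1) {
  set.seed(seed)
  array(rnorm(C * H * W), c(C, H, W))
}
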