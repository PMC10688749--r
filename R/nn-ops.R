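# Reverse-mode primitives for the segmentation engine.
#
# All spatial layers operate on matrices of shape C x (B*H*W): one row per
# channel, columns sample-major with column-major pixel order inside each
# sample (pixel p = y + (x-1)*H).  Every *_fwd returns the output plus the
# cache its paired *_bwd needs; backward passes return exact analytic
# gradients (checked against central differences in the test suite).

.idx_cache <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  v <- builder()
  .idx_cache[[key]] <- v
  v
}

# 3x3 same-padded convolution; the im2col + GEMM kernels live in
# src/conv3.cpp.  W: array (Cout, Cin, 9) with offsets ordered (dx, dy)
# column-major over -1:1; b: length Cout.
conv3_fwd <- function(X, W, b, H, Wd, B) {
  r <- conv3_fwd_cpp(X, W, b, H, Wd, B)
  # the im2col buffer stays allocated on the C++ side (external pointer)
  # so the backward pass can reuse it without rebuilding
  list(y = r$y, cache = list(xcol = r$xcol, H = H, W = Wd, B = B))
}

conv3_bwd <- function(W, dY, cache, need_dx = TRUE) {
  r <- conv3_bwd_cpp(cache$xcol, W, dY, cache$H, cache$W, cache$B, need_dx)
  list(dx = r$dx, dW = r$dW, db = as.vector(r$db))
}

conv1x1_fwd <- function(X, W, b) list(y = W %*% X + b, cache = X)
conv1x1_bwd <- function(W, dY, X) {
  list(dx = crossprod(W, dY), dW = tcrossprod(dY, X), db = rowSums(dY))
}

# batch normalisation over (batch, spatial) per channel
bn_fwd <- function(X, gamma, beta, rmean, rvar, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc * xc)
    m <- ncol(X)
    rmean <- (1 - momentum) * rmean + momentum * mu
    # unbiased variance for the running estimate, as is conventional
    rvar <- (1 - momentum) * rvar + momentum * v * m / max(1, m - 1)
  } else {
    mu <- rmean
    v <- rvar
    xc <- X - mu
  }
  ivar <- 1 / sqrt(v + eps)
  xh <- xc * ivar
  list(y = gamma * xh + beta, cache = list(xh = xh, ivar = ivar, training = training),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(gamma, dY, cache) {
  xh <- cache$xh
  dgamma <- rowSums(dY * xh)
  dbeta <- rowSums(dY)
  dxh <- dY * gamma
  if (cache$training) {
    m <- ncol(xh)
    dX <- cache$ivar * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
  } else {
    dX <- dxh * cache$ivar
  }
  list(dx = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(X) {
  m <- X > 0
  list(y = X * m, cache = m)
}
relu_bwd <- function(dY, mask) dY * mask

sigmoid <- function(x) 1 / (1 + exp(-x))
sigmoid_bwd <- function(dY, y) dY * y * (1 - y)

gelu_fwd <- function(X) {
  r <- gelu_fwd_cpp(X)
  list(y = r$y, cache = list(x = X, ph = r$ph))
}
gelu_bwd <- function(dY, cache) {
  gelu_bwd_cpp(dY, cache$x, cache$ph)
}

# 2x2 max pooling, stride 2; H, W even
pool2_maps <- function(H, W, B) {
  .memo(sprintf("p2.%d.%d.%d", H, W, B), function() {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    HW <- H * W; HW2 <- H2 * W2
    ys <- rep.int(seq_len(H2), W2)
    xs <- rep(seq_len(W2), each = H2)
    boff <- rep((seq_len(B) - 1L) * HW, each = HW2)
    maps <- vector("list", 4L)
    k <- 0L
    for (dx in 0:1) for (dy in 0:1) {
      k <- k + 1L
      base <- (2L * ys - 1L + dy) + (2L * xs - 2L + dx) * H
      maps[[k]] <- rep.int(base, B) + boff
    }
    maps
  })
}

maxpool2_fwd <- function(X, H, W, B) {
  maps <- pool2_maps(H, W, B)
  G1 <- X[, maps[[1L]], drop = FALSE]; G2 <- X[, maps[[2L]], drop = FALSE]
  G3 <- X[, maps[[3L]], drop = FALSE]; G4 <- X[, maps[[4L]], drop = FALSE]
  Y <- pmax(G1, G2, G3, G4)
  # first-argmax tie rule, evaluated in fixed order 1..4
  wh <- matrix(4L, nrow(Y), ncol(Y))
  wh[G3 == Y] <- 3L
  wh[G2 == Y] <- 2L
  wh[G1 == Y] <- 1L
  list(y = Y, cache = list(wh = wh, H = H, W = W, B = B, C = nrow(X)))
}

maxpool2_bwd <- function(dY, cache) {
  maps <- pool2_maps(cache$H, cache$W, cache$B)
  dX <- matrix(0, cache$C, cache$B * cache$H * cache$W)
  for (k in 1:4) {
    M <- dY * (cache$wh == k)
    dX[, maps[[k]]] <- dX[, maps[[k]], drop = FALSE] + M
  }
  dX
}

# transposed 2x2 convolution, stride 2: each input pixel populates a 2x2
# output block through four independent Cout x Cin kernels
up2_maps <- function(H, W, B) {
  .memo(sprintf("u2.%d.%d.%d", H, W, B), function() {
    H2 <- 2L * H; W2 <- 2L * W
    HW <- H * W; HW2 <- H2 * W2
    ys <- rep.int(seq_len(H), W)
    xs <- rep(seq_len(W), each = H)
    boff <- rep((seq_len(B) - 1L) * HW2, each = HW)
    maps <- vector("list", 4L)
    k <- 0L
    for (dx in 0:1) for (dy in 0:1) {
      k <- k + 1L
      base <- (2L * ys - 1L + dy) + (2L * xs - 2L + dx) * H2
      maps[[k]] <- rep.int(base, B) + boff
    }
    maps
  })
}

.w4 <- function(W, k) matrix(W[, , k], dim(W)[1L], dim(W)[2L])

upconv2_fwd <- function(X, W, b, H, Wd, B) {
  maps <- up2_maps(H, Wd, B)
  Cout <- dim(W)[1L]
  Y <- matrix(0, Cout, B * 4L * H * Wd)
  for (k in 1:4) Y[, maps[[k]]] <- .w4(W, k) %*% X
  list(y = Y + b, cache = list(X = X, H = H, W = Wd, B = B))
}

upconv2_bwd <- function(W, dY, cache) {
  maps <- up2_maps(cache$H, cache$W, cache$B)
  dW <- array(0, dim = dim(W))
  dX <- matrix(0, dim(W)[2L], ncol(cache$X))
  for (k in 1:4) {
    dYk <- dY[, maps[[k]], drop = FALSE]
    dW[, , k] <- tcrossprod(dYk, cache$X)
    dX <- dX + crossprod(.w4(W, k), dYk)
  }
  list(dx = dX, dW = dW, db = rowSums(dY))
}

# 2x bilinear upsampling (half-pixel centres), parameter-free; used when the
# decoder is configured with upsample = "bilinear" (followed by a 1x1 conv)
bilin2_maps <- function(H, W, B) {
  .memo(sprintf("b2.%d.%d.%d", H, W, B), function() {
    H2 <- 2L * H; W2 <- 2L * W
    src1 <- function(n, i) {
      s <- (i - 0.5) / 2 - 0.5 + 1  # 1-based source coordinate
      lo <- pmin(pmax(floor(s), 1), n)
      hi <- pmin(lo + 1, n)
      w_hi <- pmin(pmax(s - lo, 0), 1)
      list(lo = as.integer(lo), hi = as.integer(hi), w = w_hi)
    }
    sy <- src1(H, seq_len(H2)); sx <- src1(W, seq_len(W2))
    ys_lo <- rep.int(sy$lo, W2); ys_hi <- rep.int(sy$hi, W2)
    wy <- rep.int(sy$w, W2)
    xs_lo <- rep(sx$lo, each = H2); xs_hi <- rep(sx$hi, each = H2)
    wx <- rep(sx$w, each = H2)
    HW <- H * W; HW2 <- H2 * W2
    boff <- rep((seq_len(B) - 1L) * HW, each = HW2)
    mk <- function(yy, xx) rep.int(yy + (xx - 1L) * H, B) + boff
    list(idx = list(mk(ys_lo, xs_lo), mk(ys_hi, xs_lo), mk(ys_lo, xs_hi), mk(ys_hi, xs_hi)),
         w = list(rep.int((1 - wy) * (1 - wx), B), rep.int(wy * (1 - wx), B),
                  rep.int((1 - wy) * wx, B), rep.int(wy * wx, B)))
  })
}

bilinear2_fwd <- function(X, H, W, B) {
  mp <- bilin2_maps(H, W, B)
  Y <- 0
  for (k in 1:4) {
    Y <- Y + X[, mp$idx[[k]], drop = FALSE] * rep(mp$w[[k]], each = nrow(X))
  }
  list(y = Y, cache = list(H = H, W = W, B = B, C = nrow(X)))
}

bilinear2_bwd <- function(dY, cache) {
  mp <- bilin2_maps(cache$H, cache$W, cache$B)
  dX <- matrix(0, cache$C, cache$B * cache$H * cache$W)
  for (k in 1:4) {
    M <- dY * rep(mp$w[[k]], each = cache$C)
    # scatter-add; indices may repeat where edge clamping folds sources
    acc <- rowsum(t(M), mp$idx[[k]], reorder = TRUE)
    cols <- as.integer(rownames(acc))
    dX[, cols] <- dX[, cols, drop = FALSE] + t(acc)
  }
  dX
}

# nearest-neighbour upsampling by an integer factor (feature-connection align)
nn_upsample_fwd <- function(X, H, W, B, f) {
  if (f == 1L) return(list(y = X, cache = list(H = H, W = W, B = B, f = 1L, C = nrow(X))))
  H2 <- f * H; W2 <- f * W
  yy <- rep.int(((seq_len(H2) - 1L) %/% f) + 1L, W2)
  xx <- rep(((seq_len(W2) - 1L) %/% f) + 1L, each = H2)
  HW <- H * W; HW2 <- H2 * W2
  boff <- rep((seq_len(B) - 1L) * HW, each = HW2)
  idx <- rep.int(yy + (xx - 1L) * H, B) + boff
  list(y = X[, idx, drop = FALSE],
       cache = list(H = H, W = W, B = B, f = f, C = nrow(X), idx = idx))
}

nn_upsample_bwd <- function(dY, cache) {
  if (cache$f == 1L) return(dY)
  acc <- rowsum(t(dY), cache$idx, reorder = TRUE)
  dX <- matrix(0, cache$C, cache$B * cache$H * cache$W)
  cols <- as.integer(rownames(acc))
  dX[, cols] <- t(acc)
  dX
}

linear_fwd <- function(X, W, b) list(y = W %*% X + b, cache = X)
linear_bwd <- function(W, dY, X) {
  list(dx = crossprod(W, dY), dW = tcrossprod(dY, X), db = rowSums(dY))
}

# row-wise softmax with backward
softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}
softmax_rows_bwd <- function(dP, P) P * (dP - rowSums(dP * P))

# whole-matrix (instance) normalisation to zero mean / unit variance
instnorm_fwd <- function(S, eps = 1e-5) {
  mu <- mean(S)
  v <- mean((S - mu)^2)
  isd <- 1 / sqrt(v + eps)
  z <- (S - mu) * isd
  list(y = z, cache = list(z = z, isd = isd))
}
instnorm_bwd <- function(dZ, cache) {
  z <- cache$z
  cache$isd * (dZ - mean(dZ) - z * mean(dZ * z))
}

# 1-d convolution, kernel length 3, same padding, single channel
conv1d3_fwd <- function(v, k, b) {
  # v: A x B matrix (one column per sample); k: length-3 kernel
  A <- nrow(v)
  up <- rbind(0, v[-A, , drop = FALSE])    # neighbour above (index-1)
  dn <- rbind(v[-1L, , drop = FALSE], 0)   # neighbour below (index+1)
  list(y = k[1L] * up + k[2L] * v + k[3L] * dn + b,
       cache = list(v = v, up = up, dn = dn))
}
conv1d3_bwd <- function(k, dY, cache) {
  A <- nrow(dY)
  dv <- k[2L] * dY +
    k[1L] * rbind(dY[-1L, , drop = FALSE], 0) +
    k[3L] * rbind(0, dY[-A, , drop = FALSE])
  dk <- c(sum(dY * cache$up), sum(dY * cache$v), sum(dY * cache$dn))
  list(dv = dv, dk = dk, db = sum(dY))
}

# He-uniform initialisation for an array with fan_in inputs
he_uniform <- function(dim, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dim), -lim, lim), dim = dim)
}
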