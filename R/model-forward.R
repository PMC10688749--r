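# Full forward pass.  All activations are C x (B*H*W) matrices (square
# spatial grids).  Every composite block returns its output together with
# the cache consumed by the matching *_bwd in model-backward.R.

dconv_fwd <- function(p, stenv, pre, X, H, B, training) {
  g1 <- p[[paste0(pre, ".bn1.gamma")]]; g2 <- p[[paste0(pre, ".bn2.gamma")]]
  c1 <- conv3_fwd(X, p[[paste0(pre, ".conv1.W")]], p[[paste0(pre, ".conv1.b")]], H, H, B)
  b1 <- bn_fwd(c1$y, g1, p[[paste0(pre, ".bn1.beta")]],
               stenv$s[[paste0(pre, ".bn1.rmean")]], stenv$s[[paste0(pre, ".bn1.rvar")]],
               training)
  stenv$s[[paste0(pre, ".bn1.rmean")]] <- b1$rmean
  stenv$s[[paste0(pre, ".bn1.rvar")]] <- b1$rvar
  r1 <- relu_fwd(b1$y)
  c2 <- conv3_fwd(r1$y, p[[paste0(pre, ".conv2.W")]], p[[paste0(pre, ".conv2.b")]], H, H, B)
  b2 <- bn_fwd(c2$y, g2, p[[paste0(pre, ".bn2.beta")]],
               stenv$s[[paste0(pre, ".bn2.rmean")]], stenv$s[[paste0(pre, ".bn2.rvar")]],
               training)
  stenv$s[[paste0(pre, ".bn2.rmean")]] <- b2$rmean
  stenv$s[[paste0(pre, ".bn2.rvar")]] <- b2$rvar
  r2 <- relu_fwd(b2$y)
  list(y = r2$y, cache = list(c1 = c1$cache, b1 = b1$cache, m1 = r1$cache,
                              c2 = c2$cache, b2 = b2$cache, m2 = r2$cache))
}

# ---- directional global average pooling -------------------------------------

dirpool_fwd <- function(X, H, W, B, dir) {
  C <- nrow(X)
  HW <- H * W
  if (dir == "c") {
    v <- vapply(seq_len(B), function(b)
      rowMeans(X[, ((b - 1L) * HW + 1L):(b * HW), drop = FALSE]), numeric(C))
    return(matrix(v, C, B))
  }
  cm <- colMeans(X)
  if (dir == "h") {
    v <- vapply(seq_len(B), function(b)
      rowMeans(matrix(cm[((b - 1L) * HW + 1L):(b * HW)], H, W)), numeric(H))
    matrix(v, H, B)
  } else if (dir == "w") {
    v <- vapply(seq_len(B), function(b)
      colMeans(matrix(cm[((b - 1L) * HW + 1L):(b * HW)], H, W)), numeric(W))
    matrix(v, W, B)
  } else {
    stop("unknown pooling direction '", dir, "' (use 'height', 'width' or 'channel')",
         call. = FALSE)
  }
}

dirpool_bwd <- function(dv, H, W, B, C, dir) {
  HW <- H * W
  if (dir == "c") {
    return(dv[, rep(seq_len(B), each = HW), drop = FALSE] / HW)
  }
  if (dir == "h") {
    dpix <- as.vector(vapply(seq_len(B), function(b) rep.int(dv[, b] / W, W), numeric(HW)))
  } else {
    dpix <- as.vector(vapply(seq_len(B), function(b) rep(dv[, b] / H, each = H), numeric(HW)))
  }
  matrix(dpix / C, C, B * HW, byrow = TRUE)
}

# ---- patch tokenisation ------------------------------------------------------

patch_maps <- function(H, P, B) {
  .memo(sprintf("pm.%d.%d.%d", H, P, B), function() {
    nh <- H %/% P
    n <- nh * nh
    HW <- H * H
    ty <- rep.int(seq_len(nh), nh)
    tx <- rep(seq_len(nh), each = nh)
    boff <- rep((seq_len(B) - 1L) * HW, each = n)
    maps <- vector("list", P * P)
    j <- 0L
    for (px in seq_len(P)) for (py in seq_len(P)) {
      j <- j + 1L
      y <- (ty - 1L) * P + py
      x <- (tx - 1L) * P + px
      maps[[j]] <- rep.int(y + (x - 1L) * H, B) + boff
    }
    maps
  })
}

patch_gather <- function(X, H, B, P) {
  C <- nrow(X)
  maps <- patch_maps(H, P, B)
  n <- (H %/% P)^2L
  Pm <- matrix(0, C * P * P, n * B)
  for (j in seq_len(P * P)) {
    Pm[((j - 1L) * C + 1L):(j * C), ] <- X[, maps[[j]], drop = FALSE]
  }
  Pm
}

patch_scatter <- function(R, H, B, P, C) {
  maps <- patch_maps(H, P, B)
  X <- matrix(0, C, B * H * H)
  for (j in seq_len(P * P)) {
    X[, maps[[j]]] <- R[((j - 1L) * C + 1L):(j * C), , drop = FALSE]
  }
  X
}

# ---- channel cross-fusion ----------------------------------------------------

# Batched kernel of channel-wise cross attention for one (direction, head):
# per sample, scores S = Q_b %*% t(K_b) (embed x embed), instance-normalised,
# row-softmaxed over the key axis, CA_b = A %*% V_b.
attn_fwd <- function(Q, K, V, n, B) {
  CA <- matrix(0, nrow(Q), ncol(Q))
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * n + 1L):(b * n)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])
    inz <- instnorm_fwd(S)
    A <- softmax_rows(inz$y)
    CA[, cols] <- A %*% V[, cols, drop = FALSE]
    caches[[b]] <- list(A = A, inz = inz$cache)
  }
  list(y = CA, caches = caches)
}

attn_bwd <- function(dCA, Q, K, V, caches, n, B) {
  dQ <- matrix(0, nrow(Q), ncol(Q))
  dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * n + 1L):(b * n)
    A <- caches[[b]]$A
    dCAb <- dCA[, cols, drop = FALSE]
    Vb <- V[, cols, drop = FALSE]
    dA <- tcrossprod(dCAb, Vb)
    dV[, cols] <- crossprod(A, dCAb)
    dZ <- softmax_rows_bwd(dA, A)
    dS <- instnorm_bwd(dZ, caches[[b]]$inz)
    dQ[, cols] <- dS %*% K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, Q[, cols, drop = FALSE])
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

lp_fwd <- function(p, pre, U) {
  f1 <- linear_fwd(U, p[[paste0(pre, ".fc1.W")]], p[[paste0(pre, ".fc1.b")]])
  g <- gelu_fwd(f1$y)
  f2 <- linear_fwd(g$y, p[[paste0(pre, ".fc2.W")]], p[[paste0(pre, ".fc2.b")]])
  list(y = f2$y, cache = list(f1 = f1$cache, g = g$cache, f2 = f2$cache))
}

ccf_forward <- function(model, Elist, B, sizes, training) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  E <- cfg$embed_dim
  N <- cfg$heads_N
  ps <- cfg_patch_sizes(cfg)
  n <- (sizes[1L] %/% cfg$patch_size)^2L
  dirs <- c("h", "w", "c")

  # tokens: base patch embedding per stage, then per-direction context
  Pm <- vector("list", d); T0 <- vector("list", d)
  for (i in seq_len(d)) {
    Pm[[i]] <- patch_gather(Elist[[i]], sizes[i], B, ps[i])
    T0[[i]] <- p[[sprintf("ccf.emb.s%d.W", i)]] %*% Pm[[i]] + p[[sprintf("ccf.emb.s%d.b", i)]]
  }

  lrc <- NULL
  Tok <- list()
  if (cfg_has_lr(cfg)) {
    lrc <- lr_context_forward(model, Elist, B, sizes)
    for (dd in dirs) {
      Tok[[dd]] <- vector("list", d)
      for (i in seq_len(d)) {
        Tok[[dd]][[i]] <- T0[[i]] + lrc$ctx[[dd]][[i]][, rep(seq_len(B), each = n), drop = FALSE]
      }
    }
  } else {
    for (dd in dirs) Tok[[dd]] <- T0
  }

  # four-scale concatenation, folded to per-token means for the key/value path
  Tbar <- lapply(Tok, function(tl) Reduce(`+`, tl) / d)

  # attention heads
  Q <- list(); Ah <- list()
  NCA <- list(); Qbar <- list()
  for (dd in dirs) {
    NCA[[dd]] <- vector("list", d)
    Qbar[[dd]] <- vector("list", d)
    Q[[dd]] <- list(); Ah[[dd]] <- list()
    for (h in seq_len(N)) {
      wq <- p[[sprintf("ccf.attn.%s.%d.Wq", dd, h)]]
      wk <- p[[sprintf("ccf.attn.%s.%d.Wk", dd, h)]]
      wv <- p[[sprintf("ccf.attn.%s.%d.Wv", dd, h)]]
      K <- crossprod(wk, Tbar[[dd]])
      V <- crossprod(wv, Tbar[[dd]])
      Q[[dd]][[h]] <- vector("list", d)
      Ah[[dd]][[h]] <- list(K = K, V = V, st = vector("list", d))
      for (i in seq_len(d)) {
        Qi <- crossprod(wq, Tok[[dd]][[i]])
        Q[[dd]][[h]][[i]] <- Qi
        at <- attn_fwd(Qi, K, V, n, B)
        Ah[[dd]][[h]]$st[[i]] <- at$caches
        NCA[[dd]][[i]] <- if (h == 1L) at$y / N else NCA[[dd]][[i]] + at$y / N
        Qbar[[dd]][[i]] <- if (h == 1L) Qi / N else Qbar[[dd]][[i]] + Qi / N
      }
    }
  }

  # perceptron fusion over the three directions, then un-patch
  O <- vector("list", d)
  lpc <- vector("list", d)
  Usum <- vector("list", d)
  for (i in seq_len(d)) {
    acc <- 0
    lpc[[i]] <- list()
    for (dd in dirs) {
      lp <- lp_fwd(p, sprintf("ccf.lp.s%d", i), Qbar[[dd]][[i]] + NCA[[dd]][[i]])
      lpc[[i]][[dd]] <- lp$cache
      acc <- acc + NCA[[dd]][[i]] + lp$y
    }
    Usum[[i]] <- acc
    R <- p[[sprintf("ccf.unemb.s%d.W", i)]] %*% acc + p[[sprintf("ccf.unemb.s%d.b", i)]]
    O[[i]] <- patch_scatter(R, sizes[i], B, ps[i], nrow(Elist[[i]]))
  }

  list(O = O, cache = list(Pm = Pm, T0 = T0, Tok = Tok, Tbar = Tbar, Q = Q,
                           Ah = Ah, NCA = NCA, Qbar = Qbar, lpc = lpc,
                           Usum = Usum, lrc = lrc, n = n))
}

# ---- tensor low-rank context -------------------------------------------------

# For each stage and direction: global average pooling to a 1-d profile, L
# distinct conv1d+sigmoid generators, sum of the L rank-1 vectors projected
# to the shared embedding width.
lr_context_forward <- function(model, Elist, B, sizes) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  L <- cfg$rank_L
  dirs <- c("h", "w", "c")
  ctx <- list(); cache <- list()
  for (dd in dirs) {
    ctx[[dd]] <- vector("list", d)
    cache[[dd]] <- vector("list", d)
    for (i in seq_len(d)) {
      H <- sizes[i]
      v <- dirpool_fwd(Elist[[i]], H, H, B, dd)
      ssum <- 0
      gens <- vector("list", L)
      for (l in seq_len(L)) {
        cv <- conv1d3_fwd(v, p[[sprintf("lr.s%d.%s.k%d", i, dd, l)]],
                          p[[sprintf("lr.s%d.%s.kb%d", i, dd, l)]])
        sg <- sigmoid(cv$y)
        gens[[l]] <- list(cv = cv$cache, sg = sg)
        ssum <- ssum + sg
      }
      ctx[[dd]][[i]] <- p[[sprintf("lr.s%d.%s.P", i, dd)]] %*% ssum
      cache[[dd]][[i]] <- list(v = v, gens = gens, ssum = ssum)
    }
  }
  list(ctx = ctx, cache = cache)
}

# ---- feature connection ------------------------------------------------------

fc_forward <- function(model, i, O, D, H, B, training) {
  p <- model$params
  C <- nrow(O)
  HW <- H * H
  al <- conv3_fwd(O, p[[sprintf("fc.s%d.align.W", i)]],
                  p[[sprintf("fc.s%d.align.b", i)]], H, H, B)
  gO <- dirpool_fwd(al$y, H, H, B, "c")
  gD <- dirpool_fwd(D, H, H, B, "c")
  a <- p[[sprintf("fc.s%d.lin1.W", i)]] %*% gO + p[[sprintf("fc.s%d.lin1.b", i)]] +
       p[[sprintf("fc.s%d.lin2.W", i)]] %*% gD + p[[sprintf("fc.s%d.lin2.b", i)]]
  g <- sigmoid(a)
  gB <- g[, rep(seq_len(B), each = HW), drop = FALSE]
  top <- if (model$config$fc_mode == "gate") al$y * gB else al$y + gB
  list(y = rbind(top, D),
       cache = list(al = al$cache, alY = al$y, gO = gO, gD = gD, g = g,
                    gB = gB, H = H, B = B, C = C))
}

# ---- whole network -----------------------------------------------------------

prob_head <- function(logits, out_classes) {
  if (out_classes == 1L) {
    sigmoid(logits)
  } else {
    m <- apply(logits, 2L, max)
    Z <- exp(sweep(logits, 2L, m))
    sweep(Z, 2L, colSums(Z), "/")
  }
}

net_forward <- function(model, X, B, H, training = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  check_input_size(cfg, H)
  stenv <- new.env(parent = emptyenv())
  stenv$s <- model$state
  sizes <- cfg_stage_sizes(cfg, H)

  # encoder
  Elist <- vector("list", d)
  enc <- vector("list", d)
  pools <- vector("list", d)
  cur <- X
  for (i in seq_len(d)) {
    dc <- dconv_fwd(p, stenv, sprintf("enc.s%d", i), cur, sizes[i], B, training)
    Elist[[i]] <- dc$y
    enc[[i]] <- dc$cache
    mp <- maxpool2_fwd(dc$y, sizes[i], sizes[i], B)
    pools[[i]] <- mp$cache
    cur <- mp$y
  }
  bt <- dconv_fwd(p, stenv, "enc.bott", cur, sizes[d] %/% 2L, B, training)
  Xb <- bt$y

  # skip source
  ccf <- NULL
  O <- Elist
  if (cfg_has_ccf(cfg)) {
    ccf <- ccf_forward(model, Elist, B, sizes, training)
    O <- ccf$O
  }

  # decoder
  dec <- vector("list", d)
  Dlist <- vector("list", d)
  fcc <- vector("list", d)
  cur <- Xb
  for (i in rev(seq_len(d))) {
    hlow <- sizes[i] %/% 2L
    if (cfg$upsample == "transposed") {
      up <- upconv2_fwd(cur, p[[sprintf("dec.s%d.up.W", i)]],
                        p[[sprintf("dec.s%d.up.b", i)]], hlow, hlow, B)
      upc <- up$cache
    } else {
      bl <- bilinear2_fwd(cur, hlow, hlow, B)
      cv <- conv1x1_fwd(bl$y, p[[sprintf("dec.s%d.up.W", i)]],
                        p[[sprintf("dec.s%d.up.b", i)]])
      up <- list(y = cv$y)
      upc <- list(bl = bl$cache, x1 = cv$cache)
    }
    Dlist[[i]] <- up$y
    if (cfg_has_fc(cfg)) {
      fc <- fc_forward(model, i, O[[i]], up$y, sizes[i], B, training)
      skip <- fc$y
      fcc[[i]] <- fc$cache
    } else {
      skip <- rbind(O[[i]], up$y)
    }
    dc <- dconv_fwd(p, stenv, sprintf("dec.s%d", i), skip, sizes[i], B, training)
    dec[[i]] <- list(up = upc, dconv = dc$cache)
    cur <- dc$y
  }
  hd <- linear_fwd(cur, p[["head.W"]], p[["head.b"]])
  logits <- hd$y
  list(logits = logits, prob = prob_head(logits, cfg$out_classes),
       E = Elist, bottleneck = Xb, O = O, D = Dlist,
       cache = list(enc = enc, pools = pools, bott = bt$cache, ccf = ccf,
                    dec = dec, fcc = fcc, head = hd$cache, sizes = sizes,
                    B = B, H = H),
       state = stenv$s)
}

check_input_size <- function(cfg, H) {
  div <- 2L^cfg$depth
  if (H %% div != 0L) {
    stop_dim("input spatial size %d is not divisible by 2^depth = %d", H, div)
  }
  if (cfg_has_ccf(cfg) && H %% cfg$patch_size != 0L) {
    stop_dim("input spatial size %d is not divisible by patch_size = %d", H, cfg$patch_size)
  }
  if (cfg_has_lr(cfg) && H != cfg$input_size) {
    stop_dim("the low-rank variant is built for input size %d but received %d",
             cfg$input_size, H)
  }
  invisible(TRUE)
}
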