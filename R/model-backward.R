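# Reverse-mode pass through the whole network.  Gradients are accumulated
# into an environment keyed by parameter name; the result is a named list
# aligned with model$params.

gnew <- function() new.env(parent = emptyenv())

gadd <- function(gr, name, v) {
  cur <- gr[[name]]
  gr[[name]] <- if (is.null(cur)) v else cur + v
  invisible(NULL)
}

gr_as_list <- function(gr, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) {
    g <- gr[[nm]]
    out[[nm]] <- if (is.null(g)) params[[nm]] * 0 else g
  }
  out
}

dconv_bwd <- function(p, gr, pre, cache, dY, need_dx = TRUE) {
  dr2 <- relu_bwd(dY, cache$m2)
  b2 <- bn_bwd(p[[paste0(pre, ".bn2.gamma")]], dr2, cache$b2)
  gadd(gr, paste0(pre, ".bn2.gamma"), b2$dgamma)
  gadd(gr, paste0(pre, ".bn2.beta"), b2$dbeta)
  c2 <- conv3_bwd(p[[paste0(pre, ".conv2.W")]], b2$dx, cache$c2)
  gadd(gr, paste0(pre, ".conv2.W"), c2$dW)
  gadd(gr, paste0(pre, ".conv2.b"), c2$db)
  dr1 <- relu_bwd(c2$dx, cache$m1)
  b1 <- bn_bwd(p[[paste0(pre, ".bn1.gamma")]], dr1, cache$b1)
  gadd(gr, paste0(pre, ".bn1.gamma"), b1$dgamma)
  gadd(gr, paste0(pre, ".bn1.beta"), b1$dbeta)
  c1 <- conv3_bwd(p[[paste0(pre, ".conv1.W")]], b1$dx, cache$c1, need_dx = need_dx)
  gadd(gr, paste0(pre, ".conv1.W"), c1$dW)
  gadd(gr, paste0(pre, ".conv1.b"), c1$db)
  c1$dx
}

lp_bwd <- function(p, gr, pre, cache, dY) {
  l2 <- linear_bwd(p[[paste0(pre, ".fc2.W")]], dY, cache$f2)
  gadd(gr, paste0(pre, ".fc2.W"), l2$dW)
  gadd(gr, paste0(pre, ".fc2.b"), l2$db)
  dg <- gelu_bwd(l2$dx, cache$g)
  l1 <- linear_bwd(p[[paste0(pre, ".fc1.W")]], dg, cache$f1)
  gadd(gr, paste0(pre, ".fc1.W"), l1$dW)
  gadd(gr, paste0(pre, ".fc1.b"), l1$db)
  l1$dx
}

lr_context_backward <- function(model, gr, cache, dctx, B, sizes) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  L <- cfg$rank_L
  dE <- vector("list", d)
  ch <- cfg_channels(cfg)
  for (dd in c("h", "w", "c")) {
    for (i in seq_len(d)) {
      cc <- cache[[dd]][[i]]
      H <- sizes[i]
      Pn <- sprintf("lr.s%d.%s.P", i, dd)
      gadd(gr, Pn, tcrossprod(dctx[[dd]][[i]], cc$ssum))
      dssum <- crossprod(p[[Pn]], dctx[[dd]][[i]])
      dv <- 0
      for (l in seq_len(L)) {
        sg <- cc$gens[[l]]$sg
        dz <- dssum * sg * (1 - sg)
        cb <- conv1d3_bwd(p[[sprintf("lr.s%d.%s.k%d", i, dd, l)]], dz, cc$gens[[l]]$cv)
        gadd(gr, sprintf("lr.s%d.%s.k%d", i, dd, l), cb$dk)
        gadd(gr, sprintf("lr.s%d.%s.kb%d", i, dd, l), cb$db)
        dv <- dv + cb$dv
      }
      inc <- dirpool_bwd(dv, H, H, B, ch[i], dd)
      dE[[i]] <- if (is.null(dE[[i]])) inc else dE[[i]] + inc
    }
  }
  dE
}

ccf_backward <- function(model, gr, cc, dO, B, sizes) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  N <- cfg$heads_N
  ps <- cfg_patch_sizes(cfg)
  ch <- cfg_channels(cfg)
  n <- cc$n
  dirs <- c("h", "w", "c")

  dNCA <- list(); dQbar <- list()
  for (dd in dirs) { dNCA[[dd]] <- vector("list", d); dQbar[[dd]] <- vector("list", d) }

  # un-patch + perceptron fusion
  for (i in seq_len(d)) {
    dR <- patch_gather(dO[[i]], sizes[i], B, ps[i])
    gadd(gr, sprintf("ccf.unemb.s%d.W", i), tcrossprod(dR, cc$Usum[[i]]))
    gadd(gr, sprintf("ccf.unemb.s%d.b", i), rowSums(dR))
    dU <- crossprod(p[[sprintf("ccf.unemb.s%d.W", i)]], dR)
    for (dd in dirs) {
      dUin <- lp_bwd(p, gr, sprintf("ccf.lp.s%d", i), cc$lpc[[i]][[dd]], dU)
      dNCA[[dd]][[i]] <- dU + dUin
      dQbar[[dd]][[i]] <- dUin
    }
  }

  # attention
  dTok <- list()
  for (dd in dirs) dTok[[dd]] <- vector("list", d)
  for (dd in dirs) {
    dTbar <- 0
    for (h in seq_len(N)) {
      wq <- p[[sprintf("ccf.attn.%s.%d.Wq", dd, h)]]
      wk <- p[[sprintf("ccf.attn.%s.%d.Wk", dd, h)]]
      wv <- p[[sprintf("ccf.attn.%s.%d.Wv", dd, h)]]
      K <- cc$Ah[[dd]][[h]]$K
      V <- cc$Ah[[dd]][[h]]$V
      dK <- 0; dV <- 0
      for (i in seq_len(d)) {
        Qi <- cc$Q[[dd]][[h]][[i]]
        ab <- attn_bwd(dNCA[[dd]][[i]] / N, Qi, K, V, cc$Ah[[dd]][[h]]$st[[i]], n, B)
        dQi <- ab$dQ + dQbar[[dd]][[i]] / N
        dK <- dK + ab$dK
        dV <- dV + ab$dV
        gadd(gr, sprintf("ccf.attn.%s.%d.Wq", dd, h), tcrossprod(cc$Tok[[dd]][[i]], dQi))
        inc <- wq %*% dQi
        dTok[[dd]][[i]] <- if (is.null(dTok[[dd]][[i]])) inc else dTok[[dd]][[i]] + inc
      }
      gadd(gr, sprintf("ccf.attn.%s.%d.Wk", dd, h), tcrossprod(cc$Tbar[[dd]], dK))
      gadd(gr, sprintf("ccf.attn.%s.%d.Wv", dd, h), tcrossprod(cc$Tbar[[dd]], dV))
      dTbar <- dTbar + wk %*% dK + wv %*% dV
    }
    for (i in seq_len(d)) dTok[[dd]][[i]] <- dTok[[dd]][[i]] + dTbar / d
  }

  # token embedding (+ low-rank context)
  dE <- vector("list", d)
  if (cfg_has_lr(cfg)) {
    dctx <- list()
    for (dd in dirs) {
      dctx[[dd]] <- vector("list", d)
      for (i in seq_len(d)) {
        dt <- dTok[[dd]][[i]]
        # sum token columns per sample
        dctx[[dd]][[i]] <- vapply(seq_len(B), function(b)
          rowSums(dt[, ((b - 1L) * n + 1L):(b * n), drop = FALSE]),
          numeric(nrow(dt)))
        dctx[[dd]][[i]] <- matrix(dctx[[dd]][[i]], nrow(dt), B)
      }
    }
    dE <- lr_context_backward(model, gr, cc$lrc$cache, dctx, B, sizes)
  }
  for (i in seq_len(d)) {
    dT0 <- Reduce(`+`, lapply(dirs, function(dd) dTok[[dd]][[i]]))
    gadd(gr, sprintf("ccf.emb.s%d.W", i), tcrossprod(dT0, cc$Pm[[i]]))
    gadd(gr, sprintf("ccf.emb.s%d.b", i), rowSums(dT0))
    dPm <- crossprod(p[[sprintf("ccf.emb.s%d.W", i)]], dT0)
    inc <- patch_scatter(dPm, sizes[i], B, ps[i], ch[i])
    dE[[i]] <- if (is.null(dE[[i]])) inc else dE[[i]] + inc
  }
  dE
}

fc_bwd <- function(model, gr, i, cache, dOut) {
  p <- model$params
  C <- cache$C
  H <- cache$H
  B <- cache$B
  HW <- H * H
  dtop <- dOut[seq_len(C), , drop = FALSE]
  dD <- dOut[(C + 1L):(2L * C), , drop = FALSE]
  if (model$config$fc_mode == "gate") {
    dAl <- dtop * cache$gB
    dgB <- dtop * cache$alY
  } else {
    dAl <- dtop
    dgB <- dtop
  }
  dg <- vapply(seq_len(B), function(b)
    rowSums(dgB[, ((b - 1L) * HW + 1L):(b * HW), drop = FALSE]), numeric(C))
  dg <- matrix(dg, C, B)
  da <- dg * cache$g * (1 - cache$g)
  l1n <- sprintf("fc.s%d.lin1", i); l2n <- sprintf("fc.s%d.lin2", i)
  gadd(gr, paste0(l1n, ".W"), tcrossprod(da, cache$gO))
  gadd(gr, paste0(l1n, ".b"), rowSums(da))
  gadd(gr, paste0(l2n, ".W"), tcrossprod(da, cache$gD))
  gadd(gr, paste0(l2n, ".b"), rowSums(da))
  dgO <- crossprod(p[[paste0(l1n, ".W")]], da)
  dgD <- crossprod(p[[paste0(l2n, ".W")]], da)
  dAl <- dAl + dirpool_bwd(dgO, H, H, B, C, "c")
  dD <- dD + dirpool_bwd(dgD, H, H, B, C, "c")
  cb <- conv3_bwd(p[[sprintf("fc.s%d.align.W", i)]], dAl, cache$al)
  gadd(gr, sprintf("fc.s%d.align.W", i), cb$dW)
  gadd(gr, sprintf("fc.s%d.align.b", i), cb$db)
  list(dO = cb$dx, dD = dD)
}

net_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  gr <- gnew()
  cache <- fwd$cache
  B <- cache$B
  sizes <- cache$sizes
  ch <- cfg_channels(cfg)

  hb <- linear_bwd(p[["head.W"]], dlogits, cache$head)
  gadd(gr, "head.W", hb$dW)
  gadd(gr, "head.b", hb$db)
  dcur <- hb$dx

  dO <- vector("list", d)
  ddeep <- NULL
  for (i in seq_len(d)) {
    dskip <- dconv_bwd(p, gr, sprintf("dec.s%d", i), cache$dec[[i]]$dconv, dcur)
    if (cfg_has_fc(cfg)) {
      fb <- fc_bwd(model, gr, i, cache$fcc[[i]], dskip)
      dO[[i]] <- fb$dO
      dD <- fb$dD
    } else {
      dO[[i]] <- dskip[seq_len(ch[i]), , drop = FALSE]
      dD <- dskip[(ch[i] + 1L):(2L * ch[i]), , drop = FALSE]
    }
    hlow <- sizes[i] %/% 2L
    if (cfg$upsample == "transposed") {
      ub <- upconv2_bwd(p[[sprintf("dec.s%d.up.W", i)]], dD, cache$dec[[i]]$up)
      gadd(gr, sprintf("dec.s%d.up.W", i), ub$dW)
      gadd(gr, sprintf("dec.s%d.up.b", i), ub$db)
      dcur <- ub$dx
    } else {
      cb <- conv1x1_bwd(p[[sprintf("dec.s%d.up.W", i)]], dD, cache$dec[[i]]$up$x1)
      gadd(gr, sprintf("dec.s%d.up.W", i), cb$dW)
      gadd(gr, sprintf("dec.s%d.up.b", i), cb$db)
      dcur <- bilinear2_bwd(cb$dx, cache$dec[[i]]$up$bl)
    }
  }

  # dcur is now the gradient w.r.t. the bottleneck output
  dpool <- dconv_bwd(p, gr, "enc.bott", cache$bott, dcur)

  # skip-path gradients into the encoder features
  dE <- if (cfg_has_ccf(cfg)) {
    ccf_backward(model, gr, cache$ccf$cache, dO, B, sizes)
  } else {
    dO
  }

  for (i in rev(seq_len(d))) {
    dEi <- dE[[i]] + maxpool2_bwd(dpool, cache$pools[[i]])
    dpool <- dconv_bwd(p, gr, sprintf("enc.s%d", i), cache$enc[[i]], dEi,
                       need_dx = i > 1L)
  }

  gr_as_list(gr, model$params)
}
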