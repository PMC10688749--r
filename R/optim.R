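# Adam optimiser over the flat named parameter list.

adam_init <- function(params) {
  z <- lapply(params, function(p) p * 0)
  list(m = z, v = z, t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}
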