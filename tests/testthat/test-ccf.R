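test_that("patch embedding yields equal token counts across stages", {
  # stage sizes 64,32,16,8 with Ps=8 -> patch edges 8,4,2,1 and 64 tokens each
  set.seed(1)
  E <- 8L
  for (i in 1:4) {
    H <- 64L %/% 2L^(i - 1L)
    C <- 2L
    P <- 8L %/% 2L^(i - 1L)
    params <- list(W = matrix(rnorm(E * C * P * P), E), b = rnorm(E))
    tok <- embed_patches(rand_feature(C, H, H, seed = i), i, params, patch_size = 8L)
    expect_identical(nrow(tok), 64L)
    expect_identical(ncol(tok), E)
  }
})

test_that("a feature equal to its patch size gives exactly one token, and the identity projection flattens the patch", {
  x <- array(0, c(1, 2, 2))
  x[1, , ] <- matrix(c(1, 3, 2, 4), 2, 2)
  params <- list(W = diag(4), b = rep(0, 4))
  tok <- embed_patches(x, 1L, params, patch_size = 2L)
  expect_identical(dim(tok), c(1L, 4L))
  # flatten order: rows fastest within the patch (column-major)
  expect_equal(as.vector(tok), c(1, 3, 2, 4))
  expect_error(embed_patches(rand_feature(1, 6, 6), 1L, params, patch_size = 4L),
               "not divisible")
})

test_that("context vectors shift every token additively", {
  set.seed(2)
  params <- list(W = matrix(rnorm(8 * 4), 8), b = rnorm(8))
  x <- rand_feature(1, 4, 4, seed = 3)
  ctx <- rnorm(8)
  t0 <- embed_patches(x, 1L, params, patch_size = 2L)
  t1 <- embed_patches(x, 1L, params, patch_size = 2L, context = ctx)
  expect_equal(t1, t0 + matrix(ctx, nrow(t0), 8, byrow = TRUE), tolerance = 1e-12)
})

test_that("concat_scales stacks token sequences and round-trips by slicing", {
  one <- matrix(1:6 / 7, 1, 6)
  out <- concat_scales(list(one, one, one, one))
  expect_identical(dim(out), c(4L, 6L))
  expect_true(all(apply(out, 1, function(r) all(r == one))))
  set.seed(4)
  toks <- lapply(1:4, function(i) matrix(rnorm(64 * 6), 64, 6))
  cc <- concat_scales(toks)
  expect_identical(nrow(cc), 256L)
  for (i in 1:4) {
    expect_equal(cc[((i - 1) * 64 + 1):(i * 64), ], toks[[i]])
  }
  expect_error(concat_scales(list(matrix(0, 2, 3), matrix(0, 2, 4))),
               "mismatched embedding widths")
})

test_that("cross attention matches the brute-force oracle and conserves weight mass", {
  set.seed(5)
  E <- 6L; n <- 4L
  T_di <- matrix(rnorm(n * E), n, E)
  T_sum <- matrix(rnorm(4 * n * E), 4 * n, E)
  params <- list(W_Q = matrix(rnorm(E * E), E), W_K = matrix(rnorm(E * E), E),
                 W_V = matrix(rnorm(E * E), E))
  got <- cross_attention(T_di, T_sum, params)
  ora <- bf_cross_attention(T_di, T_sum, params$W_Q, params$W_K, params$W_V)
  expect_equal(got$ca, ora$ca, tolerance = 1e-6)
  expect_equal(got$weights, ora$weights, tolerance = 1e-6)
  expect_equal(rowSums(got$weights), rep(1, E), tolerance = 1e-6)
  expect_identical(dim(got$ca), dim(T_di))
})

test_that("identical keys give uniform attention and the mean value row", {
  E <- 4L; n <- 3L
  T_di <- matrix(rnorm(n * E), n, E)
  T_sum <- matrix(1, n, E)            # constant keys/values source
  params <- list(W_Q = diag(E), W_K = diag(E), W_V = diag(E))
  got <- cross_attention(T_di, T_sum, params)
  expect_equal(got$weights, matrix(1 / E, E, E), tolerance = 1e-9)
})

test_that("attention output is linear in the value projection", {
  set.seed(6)
  E <- 5L; n <- 4L
  T_di <- matrix(rnorm(n * E), n, E)
  T_sum <- matrix(rnorm(2 * n * E), 2 * n, E)
  params <- list(W_Q = matrix(rnorm(E * E), E), W_K = matrix(rnorm(E * E), E),
                 W_V = matrix(rnorm(E * E), E))
  base <- cross_attention(T_di, T_sum, params)
  params2 <- params
  params2$W_V <- 3 * params$W_V
  expect_equal(cross_attention(T_di, T_sum, params2)$ca, 3 * base$ca, tolerance = 1e-9)
})

test_that("multi-head averaging is the elementwise mean", {
  h1 <- matrix(c(1, 2, 3, 4), 2, 2)
  h2 <- matrix(c(5, 6, 7, 8), 2, 2)
  expect_equal(multi_head_average(list(h1)), h1)
  expect_equal(multi_head_average(list(h1, h1, h1)), h1)
  expect_equal(multi_head_average(list(h1, h2)), matrix(c(3, 4, 5, 6), 2, 2))
  expect_error(multi_head_average(list()), "non-empty")
})

test_that("perceptron fusion follows O = sum_d [NCA + LP(Q + NCA)]", {
  n <- 2L; E <- 3L
  set.seed(7)
  Q <- lapply(1:3, function(i) matrix(rnorm(n * E), n, E))
  NCA <- lapply(1:3, function(i) matrix(rnorm(n * E), n, E))
  # zero perceptron + zero NCA -> zero output
  zero <- lapply(1:3, function(i) matrix(0, n, E))
  lp0 <- list(W1 = matrix(0, 2 * E, E), b1 = rep(0, 2 * E),
              W2 = matrix(0, E, 2 * E), b2 = rep(0, E))
  expect_equal(fuse_stage(Q, zero, lp0), matrix(0, n, E))
  # identity-like LP (W2 %*% gelu(W1 x) with W1 = [I;0]/Phi trick is fiddly;
  # instead exploit linearity at zero bias with scaled identity blocks)
  # symbolic check: with LP == identity, O = sum_d (2 NCA_d + Q_d)
  lp_id <- function(X) X
  manual <- Reduce(`+`, lapply(1:3, function(j) NCA[[j]] + lp_id(Q[[j]] + NCA[[j]])))
  expect_equal(manual, Reduce(`+`, lapply(1:3, function(j) 2 * NCA[[j]] + Q[[j]])))
  # and the implementation agrees with a direct evaluation of its own LP
  lp <- list(W1 = matrix(rnorm(2 * E * E), 2 * E, E), b1 = rnorm(2 * E),
             W2 = matrix(rnorm(E * 2 * E), E, 2 * E), b2 = rnorm(E))
  gelu <- function(x) x * pnorm(x)
  direct <- 0
  for (j in 1:3) {
    u <- t(Q[[j]] + NCA[[j]])
    direct <- direct + t(NCA[[j]]) + (lp$W2 %*% gelu(lp$W1 %*% u + lp$b1) + lp$b2)
  }
  expect_equal(fuse_stage(Q, NCA, lp), t(direct), tolerance = 1e-9)
  # exactly three direction terms enter the sum
  expect_error(fuse_stage(Q[1:2], NCA, lp), "three direction")
})

test_that("token counts stay equal across stages for admissible sizes", {
  for (S in c(32L, 64L, 128L)) {
    cfg <- model_config(depth = 4L, base_channels = 2L, variant = "ccf",
                        patch_size = 8L, embed_dim = 8L, heads_N = 1L,
                        input_size = S)
    n_ref <- as.integer((S %/% 8L)^2)
    set.seed(S)
    E <- 4L
    for (i in 1:4) {
      H <- S %/% 2L^(i - 1L)
      P <- 8L %/% 2L^(i - 1L)
      params <- list(W = matrix(rnorm(E * 2L * P * P), E), b = rnorm(E))
      tok <- embed_patches(rand_feature(2L, H, H, seed = i), i, params, patch_size = 8L)
      expect_identical(nrow(tok), n_ref)
    }
  }
})

test_that("patch embed then un-patch with identity projections is the identity", {
  x <- rand_feature(1, 8, 8, seed = 9)
  P <- 4L
  params <- list(W = diag(P * P), b = rep(0, P * P))
  tok <- embed_patches(x, 1L, params, patch_size = P)
  back <- tlrseg:::patch_scatter(t(tok), 8L, 1L, P, 1L)
  expect_equal(array(back, dim(x)), x, tolerance = 1e-12)
})
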