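test_that("encoder produces the geometric channel/size schedule", {
  for (depth in 2:4) {
    cfg <- model_config(depth = depth, base_channels = 4L, variant = "baseline",
                        patch_size = 8L, input_size = 32L)
    model <- build_model(cfg, seed = 1L)
    img <- matrix(runif(32 * 32), 32, 32)
    enc <- encode(img, model)
    expect_length(enc$stages, depth)
    for (i in seq_len(depth)) {
      expect_identical(dim(enc$stages[[i]]),
                       as.integer(c(4 * 2^(i - 1), 32 / 2^(i - 1), 32 / 2^(i - 1))))
    }
    expect_identical(dim(enc$bottleneck)[1], as.integer(4 * 2^depth))
    expect_identical(dim(enc$bottleneck)[2], as.integer(32 / 2^depth))
  }
})

test_that("encoder outputs are finite, even for all-zero input", {
  cfg <- model_config(depth = 4L, base_channels = 16L, variant = "baseline")
  model <- build_model(cfg, seed = 2L)
  enc <- encode(matrix(0, 64, 64), model)
  expect_identical(vapply(enc$stages, function(s) dim(s)[1L], integer(1)),
                   c(16L, 32L, 64L, 128L))
  expect_identical(vapply(enc$stages, function(s) dim(s)[2L], integer(1)),
                   c(64L, 32L, 16L, 8L))
  for (s in enc$stages) expect_true(all(is.finite(s)))
  expect_true(all(is.finite(enc$bottleneck)))
})

test_that("stage-1 output equals a straight-line conv/bn/relu re-execution", {
  set.seed(5)
  cfg <- model_config(depth = 2L, base_channels = 3L, variant = "baseline",
                      patch_size = 2L, input_size = 8L)
  model <- build_model(cfg, seed = 9L)
  img <- matrix(runif(64), 8, 8)
  enc <- encode(img, model)

  p <- model$params
  bn_eval <- function(y, pre) {
    # fresh model: running mean 0, running var 1
    g <- p[[paste0(pre, ".gamma")]]; b <- p[[paste0(pre, ".beta")]]
    for (c in seq_along(g)) y[c, , ] <- g[c] * y[c, , ] / sqrt(1 + 1e-5) + b[c]
    y
  }
  x <- array(img, c(1, 8, 8))
  y <- bf_conv3(x, p[["enc.s1.conv1.W"]], p[["enc.s1.conv1.b"]])
  y <- pmax(bn_eval(y, "enc.s1.bn1"), 0)
  y2 <- bf_conv3(y, p[["enc.s1.conv2.W"]], p[["enc.s1.conv2.b"]])
  y2 <- pmax(bn_eval(y2, "enc.s1.bn2"), 0)
  expect_equal(enc$stages[[1]], y2, tolerance = 1e-10)
})

test_that("encoder rejects inputs that do not divide through the stages", {
  cfg <- model_config(depth = 4L, base_channels = 4L, variant = "baseline")
  model <- build_model(cfg, seed = 1L)
  expect_error(encode(matrix(0, 24, 24), model), "divisible by 2\\^depth = 16")
})

test_that("decoder returns full-resolution probabilities in [0,1]", {
  cfg <- model_config(depth = 2L, base_channels = 2L, variant = "baseline",
                      patch_size = 2L, input_size = 16L)
  model <- build_model(cfg, seed = 3L)
  img <- matrix(runif(256), 16, 16)
  enc <- encode(img, model)
  out <- decode(model, enc$bottleneck, enc$stages)
  expect_identical(dim(out$prob), c(1L, 16L, 16L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  pr <- predict(model, img)
  expect_equal(matrix(out$prob[1, , ], 16, 16), pr, tolerance = 1e-10)
})

test_that("decoder reports which stage has a mismatched skip", {
  cfg <- model_config(depth = 2L, base_channels = 2L, variant = "baseline",
                      patch_size = 2L, input_size = 16L)
  model <- build_model(cfg, seed = 3L)
  enc <- encode(matrix(runif(256), 16, 16), model)
  bad <- enc$stages
  bad[[2]] <- bad[[2]][, 1:4, 1:4, drop = FALSE]
  expect_error(decode(model, enc$bottleneck, bad), "stage 2")
})

test_that("probability head maps zero scores to 0.5 and softmax sums to one", {
  expect_equal(tlrseg:::prob_head(matrix(0, 1, 10), 1L), matrix(0.5, 1, 10))
  p2 <- tlrseg:::prob_head(matrix(rnorm(20), 2, 10), 2L)
  expect_equal(colSums(p2), rep(1, 10), tolerance = 1e-12)
})

test_that("predict_mask follows the tie-to-foreground rule and matches a pixel oracle", {
  expect_identical(predict_mask(matrix(0.5, 3, 3), 0.5), matrix(1L, 3, 3))
  gt <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_identical(predict_mask(gt, 0.5), gt * 1L)
  set.seed(11)
  pm <- matrix(runif(64), 8, 8)
  oracle <- matrix(0L, 8, 8)
  for (i in 1:8) for (j in 1:8) oracle[i, j] <- if (pm[i, j] >= 0.3) 1L else 0L
  expect_identical(predict_mask(pm, 0.3), oracle)
  expect_error(predict_mask(matrix(c(-0.1, 0.5), 1, 2)), "probabilities")
})

test_that("forward pass is deterministic given fixed weights and input", {
  cfg <- tiny_config()
  model <- build_model(cfg, seed = 4L)
  img <- matrix(runif(256), 16, 16)
  expect_identical(predict(model, img), predict(model, img))
})
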