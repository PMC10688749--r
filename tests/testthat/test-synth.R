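test_that("identical seeds give bit-identical corpora", {
  spec <- synthetic_spec(image_size = 32L, n_images = 4L, seed = 7L)
  a <- generate_corpus(spec)
  b <- generate_corpus(spec)
  expect_identical(a, b)
  # serialised byte streams as well
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_corpus(synthetic_spec(image_size = 32L, n_images = 4L, seed = 8L))
  expect_false(identical(a, c2))
})

test_that("a single clean disk has the expected rasterised area", {
  r <- 10
  spec <- synthetic_spec(image_size = 64L, n_images = 1L, cells_per_image = c(1L, 1L),
                         radius = c(r, r), noise_sigma = 0, seed = 3L)
  # aspect ratio varies in [0.7, 1]: area pi * r * (asp * r); bound using the
  # rasterisation tolerance of +-1 px on each semi-axis
  pair <- generate_corpus(spec)[[1]]
  area <- sum(pair$mask)
  expect_gte(area, pi * (r - 1) * (0.7 * r - 1))
  expect_lte(area, pi * (r + 1) * (r + 1))
  expect_true(all(pair$image >= 0 & pair$image <= 1))
  expect_true(all(pair$mask %in% c(0L, 1L)))
})

test_that("forced overlap keeps two cells in at most two components", {
  spec <- synthetic_spec(image_size = 64L, n_images = 6L, cells_per_image = c(2L, 2L),
                         overlap_prob = 1, noise_sigma = 0, seed = 5L)
  for (pair in generate_corpus(spec)) {
    expect_lte(bf_n_components(pair$mask), 2L)
  }
})

test_that("foreground stays class-imbalanced under the default settings", {
  spec <- synthetic_spec(image_size = 64L, n_images = 24L, seed = 9L)
  fr <- vapply(generate_corpus(spec), function(p) mean(p$mask), numeric(1))
  expect_lt(mean(fr), 0.35)
  expect_gt(mean(fr), 0.02)  # and not degenerate either
})

test_that("flip augmentation is an involution that preserves masks", {
  spec <- synthetic_spec(image_size = 32L, n_images = 1L, seed = 2L)
  pair <- generate_corpus(spec)[[1]]
  # double horizontal flip is the identity
  f <- pair$image[, rev(seq_len(32))]
  expect_identical(f[, rev(seq_len(32))], pair$image)
  # a flip moves an asymmetric single pixel to the mirrored coordinate
  pm <- matrix(0L, 8, 8); pm[2, 3] <- 1L
  set.seed(1)  # first two runif draws: 0.266 < 0.5 (h-flip), 0.372 < 0.5 (v-flip)
  got <- augment_flip(pm * 1.0, pm)
  expect_identical(which(got$mask == 1L, arr.ind = TRUE)[1, ],
                   c(row = 7L, col = 6L))
  expect_true(all(got$mask %in% c(0L, 1L)))
  # image and mask always receive the same flip: identify the applied flip
  # from the mask and check the image matches that exact transform
  flips <- list(function(m) m,
                function(m) m[, rev(seq_len(ncol(m)))],
                function(m) m[rev(seq_len(nrow(m))), ],
                function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))])
  set.seed(33)
  for (i in 1:5) {
    got <- augment_flip(pair$image, pair$mask)
    hit <- which(vapply(flips, function(f) identical(f(pair$mask), got$mask), logical(1)))
    expect_gte(length(hit), 1L)
    expect_true(any(vapply(hit, function(h)
      identical(flips[[h]](pair$image), got$image), logical(1))))
  }
  expect_error(augment_flip(matrix(0, 2, 2), matrix(0, 3, 3)), "dimensions differ")
})

test_that("corpus write/read round-trips losslessly with a consistent manifest", {
  spec <- synthetic_spec(image_size = 32L, n_images = 10L, seed = 4L)
  pairs <- generate_corpus(spec)
  dir <- file.path(tempdir(), "tlr-corpus-test")
  man <- write_corpus(pairs, dir)
  expect_identical(nrow(man), 10L)
  expect_identical(sum(man$split == "train"), 8L)
  expect_identical(sum(man$split == "val"), 1L)
  expect_identical(sum(man$split == "test"), 1L)
  expect_true(length(intersect(man$image[man$split == "train"],
                               man$image[man$split == "val"])) == 0)
  back <- read_corpus(dir)
  for (i in seq_along(pairs)) {
    # images were quantised to the 16-bit grid at generation: exact round trip
    expect_identical(max(abs(back[[i]]$image - pairs[[i]]$image)), 0)
    expect_identical(back[[i]]$mask, pairs[[i]]$mask * 1L)
  }
  tr <- read_corpus(dir, "train")
  expect_length(tr, 8L)
  # a missing pair member is reported by file name
  file.remove(file.path(dir, man$mask[2]))
  expect_error(read_corpus(dir), "mask_0002")
  unlink(dir, recursive = TRUE)
})
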