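# Synthetic cell-image corpus: bright, softly-rimmed elliptical cells on a
# darker low-frequency textured background, additive Gaussian noise, exact
# ground-truth masks.  Emulates micrographs of roundish cells (including
# touching/overlapping pairs) so the whole pipeline is testable without any
# external data.

#' Specification of a synthetic corpus
#'
#' @param image_size Square image edge in pixels (power of two).
#' @param n_images Number of image/mask pairs.
#' @param cells_per_image Integer range `c(min, max)` of cells per image.
#' @param radius Pixel range `c(min, max)` of cell semi-major radii;
#'   the maximum must stay below `image_size / 2`.
#' @param overlap_prob Probability that a cell after the first is placed
#'   touching/overlapping an existing cell.
#' @param noise_sigma Standard deviation of additive Gaussian noise, as a
#'   fraction of the unit dynamic range.
#' @param texture Amplitude of the low-frequency background texture.
#' @param seed Master seed; all per-image randomness derives from it.
#' @return Object of class `tlr_synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = 64L, n_images = 16L,
                           cells_per_image = c(1L, 6L), radius = c(5, 14),
                           overlap_prob = 0.3, noise_sigma = 0.1,
                           texture = 0.15, seed = 1L) {
  assert_that(is_pow2(image_size), "image_size must be a power of two")
  assert_that(n_images >= 1, "n_images must be >= 1")
  assert_that(max(radius) < image_size / 2,
              "maximum radius (%g) must be below image_size/2 (%g)",
              max(radius), image_size / 2)
  assert_that(overlap_prob >= 0 && overlap_prob <= 1, "overlap_prob must lie in [0, 1]")
  assert_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  structure(list(image_size = as.integer(image_size), n_images = as.integer(n_images),
                 cells_per_image = as.integer(cells_per_image), radius = radius,
                 overlap_prob = overlap_prob, noise_sigma = noise_sigma,
                 texture = texture, seed = as.integer(seed)),
            class = "tlr_synthetic_spec")
}

# smooth background: coarse Gaussian grid bilinearly interpolated to S x S
synth_background <- function(S, amplitude) {
  gn <- 5L
  g <- matrix(stats::rnorm(gn * gn), gn, gn)
  pos <- seq(1, gn, length.out = S)
  lo <- pmin(floor(pos), gn - 1L)
  fr <- pos - lo
  rows <- g[lo, , drop = FALSE] * (1 - fr) + g[lo + 1L, , drop = FALSE] * fr
  bg <- rows[, lo, drop = FALSE] * rep(1 - fr, each = S) +
        rows[, lo + 1L, drop = FALSE] * rep(fr, each = S)
  0.25 + amplitude * bg
}

synth_one <- function(spec, seed) {
  with_seed(seed, {
    S <- spec$image_size
    img <- synth_background(S, spec$texture)
    mask <- matrix(0L, S, S)
    yy <- matrix(seq_len(S), S, S)
    xx <- matrix(seq_len(S), S, S, byrow = TRUE)
    ncell <- sample(spec$cells_per_image[1L]:spec$cells_per_image[2L], 1L)
    placed <- list()
    dropped <- 0L
    for (k in seq_len(ncell)) {
      r <- stats::runif(1, spec$radius[1L], spec$radius[2L])
      asp <- stats::runif(1, 0.7, 1)
      th <- stats::runif(1, 0, pi)
      ok <- FALSE
      for (try in 1:50) {
        if (length(placed) > 0 && stats::runif(1) < spec$overlap_prob) {
          j <- placed[[sample.int(length(placed), 1L)]]
          dist <- (j$r + r) * stats::runif(1, 0.55, 0.95)
          ang <- stats::runif(1, 0, 2 * pi)
          cy <- j$cy + dist * sin(ang)
          cx <- j$cx + dist * cos(ang)
        } else {
          cy <- stats::runif(1, r, S - r)
          cx <- stats::runif(1, r, S - r)
        }
        if (cy >= 1 && cy <= S && cx >= 1 && cx <= S) { ok <- TRUE; break }
      }
      if (!ok) { dropped <- dropped + 1L; next }
      ry <- r; rx <- r * asp
      u <- (yy - cy) * cos(th) + (xx - cx) * sin(th)
      v <- -(yy - cy) * sin(th) + (xx - cx) * cos(th)
      rho <- sqrt((u / ry)^2 + (v / rx)^2)
      inten <- stats::runif(1, 0.6, 0.9)
      w <- 1.5 / r  # rim softness ~1.5 px: the cell/background edge blurs
      alpha <- pmin(pmax((1 + w - rho) / w, 0), 1)
      shade <- 0.7 + 0.3 * pmax(1 - rho^2, 0)
      img <- pmax(img, alpha * inten * shade)
      mask[rho <= 1] <- 1L
      placed[[length(placed) + 1L]] <- list(cy = cy, cx = cx, r = r)
    }
    if (dropped > 0L) {
      warning(sprintf("placed %d of %d cells after bounded retries", ncell - dropped, ncell))
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(S * S, sd = spec$noise_sigma), S, S)
    }
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 65535) / 65535  # quantise to the 16-bit storage grid
    list(image = img, mask = mask)
  })
}

#' Generate a synthetic corpus
#'
#' Produces `n_images` paired images and exact binary masks. Identical
#' seeds give bit-identical corpora. If a cell cannot be placed within a
#' bounded number of retries a warning is emitted and the image simply
#' contains fewer cells.
#'
#' @param spec A [synthetic_spec()].
#' @return List of pairs, each `list(image, mask)`: `image` is an
#'   `S x S` matrix in `[0, 1]` (quantised to the 16-bit storage grid) and
#'   `mask` an `S x S` 0/1 integer matrix.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "tlr_synthetic_spec"))
  seeds <- derive_seeds(spec$seed, spec$n_images)
  lapply(seq_len(spec$n_images), function(i) synth_one(spec, seeds[i]))
}

#' Random flip augmentation
#'
#' Applies the same randomly chosen horizontal and/or vertical flip to an
#' image and its mask (each axis independently with probability 1/2).
#' Draws from the current RNG stream; seed the caller for reproducibility.
#'
#' @param image,mask Matrices of identical dimensions.
#' @return List with the flipped `image` and `mask`.
#' @export
augment_flip <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) {
    stop_dim("image (%s) and mask (%s) dimensions differ",
             paste(dim(image), collapse = "x"), paste(dim(mask), collapse = "x"))
  }
  if (stats::runif(1) < 0.5) {  # horizontal: mirror columns
    image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (stats::runif(1) < 0.5) {  # vertical: mirror rows
    image <- image[rev(seq_len(nrow(image))), , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  list(image = image, mask = mask)
}

#' Write a corpus to disk
#'
#' Images are stored as 16-bit grayscale TIFF, masks as 8-bit PNG with
#' background 0 and foreground 255, plus a tab-separated `manifest.tsv`
#' with columns `id`, `image`, `mask`, `split`. Splits are assigned
#' contiguously in the given proportions, so they are disjoint by
#' construction.
#'
#' @param pairs List of `list(image, mask)` pairs as from
#'   [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @param split Named proportions for `train`/`val`/`test`.
#' @return The manifest `data.frame`, invisibly.
#' @export
write_corpus <- function(pairs, dir, split = c(train = 0.8, val = 0.1, test = 0.1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(pairs)
  ntr <- floor(n * split[["train"]])
  nva <- floor(n * split[["val"]])
  splits <- rep(c("train", "val", "test"), c(ntr, nva, n - ntr - nva))
  man <- data.frame(id = seq_len(n),
                    image = sprintf("img_%04d.tiff", seq_len(n)),
                    mask = sprintf("mask_%04d.png", seq_len(n)),
                    split = splits, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tiff::writeTIFF(pairs[[i]]$image, file.path(dir, man$image[i]),
                    bits.per.sample = 16L)
    png::writePNG(pairs[[i]]$mask * 1.0, file.path(dir, man$mask[i]))
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}

#' Read a corpus from disk
#'
#' @param dir Directory written by [write_corpus()].
#' @param split Optional split name (`"train"`, `"val"`, `"test"`) to
#'   restrict to.
#' @return List of `list(image, mask)` pairs with the manifest rows
#'   attached as attribute `manifest`.
#' @export
read_corpus <- function(dir, split = NULL) {
  mf <- file.path(dir, "manifest.tsv")
  assert_that(file.exists(mf), "no manifest.tsv in %s", dir)
  man <- utils::read.table(mf, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!is.null(split)) man <- man[man$split == split, , drop = FALSE]
  pairs <- lapply(seq_len(nrow(man)), function(i) {
    fi <- file.path(dir, man$image[i])
    fm <- file.path(dir, man$mask[i])
    if (!file.exists(fi)) stop("manifest names a missing image file: ", man$image[i], call. = FALSE)
    if (!file.exists(fm)) stop("manifest names a missing mask file: ", man$mask[i], call. = FALSE)
    img <- tiff::readTIFF(fi)
    msk <- png::readPNG(fm)
    list(image = img, mask = (msk > 0.5) * 1L)
  })
  attr(pairs, "manifest") <- man
  pairs
}
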