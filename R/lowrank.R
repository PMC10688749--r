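# Tensor low-rank context module: single-sample operations.

#' Directional global average pooling
#'
#' Collapses a feature map to a 1-d profile along one axis: entry `k` is
#' the arithmetic mean of every element whose index along the kept axis is
#' `k` (the other two axes are averaged out).
#'
#' @param feature `(C, H, W)` array or `H x W` matrix (1 channel).
#' @param direction `"height"`, `"width"` or `"channel"`.
#' @return Numeric vector with the length of the kept axis.
#' @export
direction_pool <- function(feature, direction) {
  a <- as_feature(feature)
  dd <- switch(direction, height = "h", width = "w", channel = "c",
               stop("unknown pooling direction '", direction,
                    "' (use 'height', 'width' or 'channel')", call. = FALSE))
  d <- dim(a)
  if (dd == "c") return(rowMeans(matrix(a, d[1L])))
  cm <- colMeans(matrix(a, d[1L]))       # mean over channels -> H x W grid
  g <- matrix(cm, d[2L], d[3L])
  if (dd == "h") rowMeans(g) else colMeans(g)
}

#' Default parameters for the rank-1 context generators
#'
#' Each generator is a kernel-3 single-channel 1-d convolution followed by
#' a sigmoid; this draws `L` independent kernels per direction.
#'
#' @param L Number of generators per direction.
#' @param seed Integer seed.
#' @return Nested list `params[[direction]][[l]]` with fields `kernel`
#'   (length 3) and `bias`.
#' @export
lr_params <- function(L, seed = 1L) {
  assert_that(L >= 1, "L must be >= 1")
  with_seed(seed, {
    out <- list()
    for (d in c("height", "width", "channel")) {
      out[[d]] <- lapply(seq_len(L), function(l)
        list(kernel = stats::runif(3L, -sqrt(2), sqrt(2)), bias = 0))
    }
    out
  })
}

#' Generate rank-1 context vectors
#'
#' Produces the low-rank context of one feature map: for each of the three
#' directions (height, width, channel), `L` distinct generators apply
#' global average pooling, a kernel-3 same-padded 1-d convolution, and a
#' sigmoid, yielding `3L` rank-1 vectors with entries in `[0, 1]`.
#'
#' @param feature `(C, H, W)` array or `H x W` matrix.
#' @param L Number of generators per direction (`>= 1`).
#' @param params Generator parameters as from [lr_params()]; drawn from
#'   `seed` when omitted.
#' @param seed Seed used when `params` is `NULL`.
#' @return Object of class `tlr_context`: list with elements `height`,
#'   `width`, `channel`, each a list of `L` vectors, plus attribute `L`.
#' @export
generate_context <- function(feature, L, params = NULL, seed = 1L) {
  assert_that(L >= 1, "L must be >= 1")
  if (is.null(params)) params <- lr_params(L, seed)
  out <- list()
  for (d in c("height", "width", "channel")) {
    v <- matrix(direction_pool(feature, d), ncol = 1L)
    out[[d]] <- lapply(seq_len(L), function(l) {
      pk <- params[[d]][[l]]
      as.vector(sigmoid(conv1d3_fwd(v, pk$kernel, pk$bias)$y))
    })
  }
  structure(out, class = "tlr_context", L = L)
}

#' @export
print.tlr_context <- function(x, ...) {
  cat(sprintf("<tlr_context> L=%d: %d+%d+%d rank-1 vectors (height/width/channel)\n",
              attr(x, "L"), length(x$height), length(x$width), length(x$channel)))
  invisible(x)
}
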