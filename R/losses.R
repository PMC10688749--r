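#' Weighted binary cross-entropy
#'
#' Pixelwise cross-entropy with a multiplier `beta` on the foreground terms,
#' `-(beta * p * log(p_hat) + (1 - p) * log(1 - p_hat))`, averaged over all
#' pixels. `beta > 1` counters foreground/background class imbalance.
#'
#' @param p_hat Predicted foreground probabilities (any numeric array),
#'   clamped to `[epsilon, 1 - epsilon]` before the logarithms.
#' @param p Ground-truth binary map of the same shape (values 0/1).
#' @param beta Positive weight applied to foreground (p = 1) terms.
#' @param epsilon Probability clamp.
#' @return Non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(p_hat, p, beta = 1, epsilon = 1e-6) {
  check_same_shape(p_hat, p, "p_hat", "p")
  check_binary(p, "p")
  assert_that(beta > 0, "beta must be positive")
  q <- pmin(pmax(p_hat, epsilon), 1 - epsilon)
  -mean(beta * p * log(q) + (1 - p) * log(1 - q))
}

wce_grad <- function(p_hat, p, beta = 1, epsilon = 1e-6) {
  q <- pmin(pmax(p_hat, epsilon), 1 - epsilon)
  g <- -(beta * p / q - (1 - p) / (1 - q)) / length(p)
  g[p_hat < epsilon | p_hat > 1 - epsilon] <- 0
  g
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p_hat * p) + epsilon) / (sum(p_hat) + sum(p) + epsilon)`,
#' the probability-valued extension of the Dice set overlap: with binary
#' inputs it reduces to `1 - 2|X n Y| / (|X| + |Y|)`.
#'
#' @inheritParams weighted_cross_entropy
#' @param epsilon Smoothing constant keeping the ratio defined for empty
#'   masks.
#' @return Scalar loss in `[0, 1)`.
#' @export
dice_loss <- function(p_hat, p, epsilon = 1e-6) {
  check_same_shape(p_hat, p, "p_hat", "p")
  inter <- sum(p_hat * p)
  denom <- sum(p_hat) + sum(p) + epsilon
  1 - (2 * inter + epsilon) / denom
}

#' Soft Dice coefficient
#'
#' The similarity `(2 * sum(p_hat * p) + epsilon) / (sum(p_hat) + sum(p) +
#' epsilon)`; `dice_loss()` is one minus this value.
#'
#' @inheritParams dice_loss
#' @return Scalar in `(0, 1]`.
#' @export
dice_coefficient <- function(p_hat, p, epsilon = 1e-6) {
  1 - dice_loss(p_hat, p, epsilon)
}

dice_grad <- function(p_hat, p, epsilon = 1e-6) {
  inter <- sum(p_hat * p)
  denom <- sum(p_hat) + sum(p) + epsilon
  ((2 * inter + epsilon) / denom^2) - 2 * p / denom
}

#' Composite training loss
#'
#' `alpha * WCE + (1 - alpha) * DiceLoss`: the blend of weighted
#' cross-entropy and soft Dice loss used for training.
#'
#' @inheritParams weighted_cross_entropy
#' @param config A [loss_config()] carrying `alpha`, `beta` and `epsilon`.
#' @return Scalar loss.
#' @export
combined_loss <- function(p_hat, p, config = loss_config()) {
  stopifnot(inherits(config, "tlr_loss_config"))
  a <- config$alpha
  wce <- if (a > 0) weighted_cross_entropy(p_hat, p, config$beta, config$epsilon) else 0
  dl <- if (a < 1) dice_loss(p_hat, p, config$epsilon) else 0
  a * wce + (1 - a) * dl
}

combined_grad <- function(p_hat, p, config = loss_config()) {
  a <- config$alpha
  g <- 0
  if (a > 0) g <- g + a * wce_grad(p_hat, p, config$beta, config$epsilon)
  if (a < 1) g <- g + (1 - a) * dice_grad(p_hat, p, config$epsilon)
  g
}

check_same_shape <- function(a, b, na, nb) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop_dim("%s and %s have mismatched dimensions (%s vs %s)",
             na, nb, paste(da, collapse = "x"), paste(db, collapse = "x"))
  }
  invisible(TRUE)
}

check_binary <- function(x, name) {
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("%s must be binary (0/1)", name), call. = FALSE)
  }
  invisible(TRUE)
}
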