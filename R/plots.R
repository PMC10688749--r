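# Base-graphics visualisation helpers.

#' Plot training curves
#'
#' Left panel: per-step training loss. Right panel: per-epoch validation
#' metrics (when recorded).
#'
#' @param fit A `tlr_fit` from [train_model()].
#' @return `fit`, invisibly.
#' @export
plot_history <- function(fit) {
  stopifnot(inherits(fit, "tlr_fit"))
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(fit$steps$step, fit$steps$loss, type = "l", col = "steelblue",
                 xlab = "step", ylab = "training loss", main = "loss")
  ep <- fit$epochs
  if (any(!is.na(ep$dice_pct))) {
    graphics::plot(ep$epoch, ep$dice_pct, type = "b", col = "darkorange",
                   ylim = c(0, 100), xlab = "epoch", ylab = "percent",
                   main = "validation metrics")
    graphics::lines(ep$epoch, ep$precision_pct, type = "b", col = "forestgreen")
    graphics::legend("bottomright", legend = c("Dice", "precision"),
                     col = c("darkorange", "forestgreen"), lty = 1, bty = "n")
  } else {
    graphics::plot(ep$epoch, ep$train_loss, type = "b", xlab = "epoch",
                   ylab = "mean loss", main = "epoch loss")
  }
  invisible(fit)
}

#' Show an image with its mask and a prediction
#'
#' @param image `H x W` matrix in `[0, 1]`.
#' @param mask Optional ground-truth 0/1 matrix.
#' @param prob Optional predicted probability map.
#' @return `NULL`, invisibly.
#' @export
plot_prediction <- function(image, mask = NULL, prob = NULL) {
  k <- 1L + !is.null(mask) + !is.null(prob)
  op <- graphics::par(mfrow = c(1, k), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, title) {
    graphics::image(t(m)[, rev(seq_len(nrow(m)))], col = grDevices::gray.colors(256, 0, 1),
                    axes = FALSE, main = title, useRaster = TRUE)
  }
  show(image, "image")
  if (!is.null(mask)) show(mask, "mask")
  if (!is.null(prob)) show(prob, "prediction")
  invisible(NULL)
}
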