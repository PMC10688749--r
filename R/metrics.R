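#' Pixel confusion counts
#'
#' Tallies true/false positives and negatives between a predicted and a
#' ground-truth binary mask (foreground = 1).
#'
#' @param pred,truth Binary arrays of identical shape.
#' @return Object of class `tlr_confusion`: list with integer fields `TP`,
#'   `FP`, `FN`, `TN` summing to the pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  check_same_shape(pred, truth, "pred", "truth")
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- length(pred) - tp - fp - fn
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn), class = "tlr_confusion")
}

confusion_add <- function(a, b) {
  structure(list(TP = a$TP + b$TP, FP = a$FP + b$FP,
                 FN = a$FN + b$FN, TN = a$TN + b$TN), class = "tlr_confusion")
}

#' @export
print.tlr_confusion <- function(x, ...) {
  cat(sprintf("<tlr_confusion> TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Segmentation metrics from confusion counts
#'
#' All four metrics are returned as percentages in `[0, 100]`.
#' `dice_score` is `100 * 2TP / (2TP + FP + FN)`; `miou_score` is the
#' foreground intersection-over-union `100 * TP / (TP + FP + FN)` (the
#' single-class form, despite the conventional "mean IoU" name);
#' `precision_score` is `100 * TP / (TP + FP)` and `recall_score`
#' `100 * TP / (TP + FN)`.
#'
#' Conventions for empty denominators: Dice and IoU of two empty masks are
#' defined as 100 (perfect agreement); precision/recall with an empty
#' denominator return `NA` and are excluded from averages.
#'
#' @param c A `tlr_confusion` from [confusion_counts()].
#' @return Numeric percentage (or `NA` for undefined precision/recall).
#' @export
dice_score <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) return(100)
  100 * 2 * c$TP / den
}

#' @rdname dice_score
#' @export
miou_score <- function(c) {
  den <- c$TP + c$FP + c$FN
  if (den == 0) return(100)
  100 * c$TP / den
}

#' @rdname dice_score
#' @export
precision_score <- function(c) {
  den <- c$TP + c$FP
  if (den == 0) return(NA_real_)
  100 * c$TP / den
}

#' @rdname dice_score
#' @export
recall_score <- function(c) {
  den <- c$TP + c$FN
  if (den == 0) return(NA_real_)
  100 * c$TP / den
}

#' One metrics table row
#'
#' @param c A `tlr_confusion`.
#' @param variant Label for the `variant` column.
#' @return A one-row `data.frame` with columns `variant`, `dice_pct`,
#'   `miou_pct`, `precision_pct`, `recall_pct`.
#' @export
metrics_row <- function(c, variant = NA_character_) {
  data.frame(variant = variant,
             dice_pct = dice_score(c),
             miou_pct = miou_score(c),
             precision_pct = precision_score(c),
             recall_pct = recall_score(c),
             stringsAsFactors = FALSE)
}
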