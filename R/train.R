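# Training loop, evaluation and the ablation harness.

batch_tensor <- function(pairs, idx) {
  # stack selected images/masks into 1 x (B*H*W) matrices
  imgs <- lapply(idx, function(i) as.vector(pairs[[i]]$image))
  msks <- lapply(idx, function(i) as.vector(pairs[[i]]$mask))
  list(x = matrix(unlist(imgs), nrow = 1L),
       y = matrix(unlist(msks), nrow = 1L),
       B = length(idx), H = nrow(pairs[[1L]]$image))
}

#' Train a segmentation model
#'
#' Adam training of the configured variant on image/mask pairs with the
#' composite loss `alpha * WCE + (1 - alpha) * Dice`. Optionally augments
#' each training sample with random flips and evaluates a validation split
#' every epoch. Runs are deterministic for a fixed seed (the engine has no
#' nondeterministic operations), which also serves as the strict
#' reproducibility mode.
#'
#' @param model A `tlr_model` from [build_model()], or a
#'   [model_config()] (a model is then built with the training seed).
#' @param train_cfg A [train_config()].
#' @param train_pairs List of `list(image, mask)` training pairs.
#' @param val_pairs Optional validation pairs.
#' @param verbose Print per-epoch progress.
#' @return Object of class `tlr_fit`: list with `model`, `steps` (per-step
#'   loss data.frame) and `epochs` (per-epoch metrics data.frame with
#'   train-loss and, when available, validation metrics).
#' @export
train_model <- function(model, train_cfg, train_pairs, val_pairs = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(train_cfg, "tlr_train_config"))
  if (inherits(model, "tlr_model_config")) {
    model <- build_model(model, seed = train_cfg$seed)
  }
  stopifnot(inherits(model, "tlr_model"))
  assert_that(length(train_pairs) > 0, "training corpus is empty")
  lcfg <- loss_config(alpha = train_cfg$alpha, beta = train_cfg$beta)
  opt <- adam_init(model$params)
  n <- length(train_pairs)
  H <- nrow(train_pairs[[1L]]$image)
  steps <- list()
  epochs <- list()
  gstep <- 0L
  eseeds <- derive_seeds(train_cfg$seed, train_cfg$epochs)
  for (ep in seq_len(train_cfg$epochs)) {
    lr <- train_cfg$learning_rate
    if (train_cfg$cosine_decay) {
      lr <- lr * 0.5 * (1 + cos(pi * (ep - 1) / train_cfg$epochs))
    }
    ep_losses <- c()
    with_seed(eseeds[ep], {
      perm <- sample.int(n)
      nb <- ceiling(n / train_cfg$batch_size)
      for (bi in seq_len(nb)) {
        idx <- perm[((bi - 1L) * train_cfg$batch_size + 1L):min(bi * train_cfg$batch_size, n)]
        pb <- lapply(train_pairs[idx], function(pr) {
          if (train_cfg$augment) augment_flip(pr$image, pr$mask) else pr
        })
        bt <- batch_tensor(pb, seq_along(pb))
        fwd <- net_forward(model, bt$x, bt$B, H, training = TRUE)
        model$state <- fwd$state
        loss <- combined_loss(fwd$prob, bt$y, lcfg)
        gstep <- gstep + 1L
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss (%.4g) at epoch %d step %d", loss, ep, gstep),
               call. = FALSE)
        }
        dprob <- combined_grad(fwd$prob, bt$y, lcfg)
        dlogits <- dprob * fwd$prob * (1 - fwd$prob)
        grads <- net_backward(model, fwd, dlogits)
        up <- adam_step(model$params, grads, opt, lr)
        model$params <- up$params
        opt <- up$st
        steps[[gstep]] <- data.frame(epoch = ep, step = gstep, loss = loss)
        ep_losses <- c(ep_losses, loss)
      }
    })
    erow <- data.frame(epoch = ep, train_loss = mean(ep_losses),
                       dice_pct = NA_real_, miou_pct = NA_real_,
                       precision_pct = NA_real_, recall_pct = NA_real_)
    if (!is.null(val_pairs) && ep %% train_cfg$val_every == 0L) {
      vm <- evaluate_model(model, val_pairs)
      erow$dice_pct <- vm$dice_pct
      erow$miou_pct <- vm$miou_pct
      erow$precision_pct <- vm$precision_pct
      erow$recall_pct <- vm$recall_pct
    }
    epochs[[ep]] <- erow
    if (verbose) {
      message(sprintf("epoch %d/%d loss %.4f val dice %s", ep, train_cfg$epochs,
                      mean(ep_losses),
                      ifelse(is.na(erow$dice_pct), "-", sprintf("%.2f%%", erow$dice_pct))))
    }
  }
  structure(list(model = model,
                 steps = do.call(rbind, steps),
                 epochs = do.call(rbind, epochs),
                 train_cfg = train_cfg),
            class = "tlr_fit")
}

#' @export
print.tlr_fit <- function(x, ...) {
  last <- x$epochs[nrow(x$epochs), ]
  cat(sprintf("<tlr_fit> %s, %d epochs, final train loss %.4f, val Dice %s\n",
              x$model$config$variant, nrow(x$epochs), last$train_loss,
              ifelse(is.na(last$dice_pct), "-", sprintf("%.2f%%", last$dice_pct))))
  invisible(x)
}

#' Evaluate a model on image/mask pairs
#'
#' Predicts each image, thresholds at `threshold`, and aggregates
#' confusion counts. `average = "micro"` (default) pools pixel counts over
#' the whole split before computing metrics; `"macro"` averages per-image
#' metrics (undefined per-image values excluded).
#'
#' @param model A `tlr_model`.
#' @param pairs List of `list(image, mask)` pairs.
#' @param average `"micro"` or `"macro"`.
#' @param threshold Mask threshold.
#' @param variant Label for the `variant` column; defaults to the model's
#'   variant.
#' @return One-row metrics `data.frame` (see [metrics_row()]) with the
#'   pooled confusion counts attached as attribute `confusion` (micro).
#' @export
evaluate_model <- function(model, pairs, average = c("micro", "macro"),
                           threshold = 0.5, variant = NULL) {
  average <- match.arg(average)
  stopifnot(inherits(model, "tlr_model"))
  assert_that(length(pairs) > 0, "evaluation corpus is empty")
  variant <- variant %||% model$config$variant
  H <- nrow(pairs[[1L]]$image)
  # batch images through the network a few at a time for speed
  bs <- 8L
  counts <- list()
  for (s in seq(1L, length(pairs), by = bs)) {
    idx <- s:min(s + bs - 1L, length(pairs))
    bt <- batch_tensor(pairs, idx)
    fwd <- net_forward(model, bt$x, bt$B, H, training = FALSE)
    pm <- predict_mask(matrix(pmin(pmax(fwd$prob, 0), 1), nrow = 1L), threshold)
    HW <- H * H
    for (j in seq_along(idx)) {
      cols <- ((j - 1L) * HW + 1L):(j * HW)
      counts[[length(counts) + 1L]] <-
        confusion_counts(pm[1L, cols], bt$y[1L, cols])
    }
  }
  if (average == "micro") {
    pooled <- Reduce(confusion_add, counts)
    out <- metrics_row(pooled, variant)
    attr(out, "confusion") <- pooled
    out
  } else {
    rows <- do.call(rbind, lapply(counts, metrics_row, variant = variant))
    out <- data.frame(variant = variant,
                      dice_pct = mean(rows$dice_pct, na.rm = TRUE),
                      miou_pct = mean(rows$miou_pct, na.rm = TRUE),
                      precision_pct = mean(rows$precision_pct, na.rm = TRUE),
                      recall_pct = mean(rows$recall_pct, na.rm = TRUE),
                      stringsAsFactors = FALSE)
    out
  }
}

#' Run the five-variant ablation
#'
#' Trains and evaluates the architecture variants on identical data with
#' an identical schedule and seed, producing the ablation table: one row
#' per variant with the display labels of [ablation_variants()].
#'
#' @param train_pairs,val_pairs Training and evaluation pairs shared by
#'   every variant.
#' @param base_cfg A [model_config()] whose `variant` field is overridden
#'   per row.
#' @param train_cfg A [train_config()] shared by every variant.
#' @param variants Character vector of variant ids (default all five).
#' @param verbose Print progress.
#' @return `data.frame` with columns `variant`, `dice_pct`, `miou_pct`,
#'   `precision_pct`, `recall_pct`; parameter counts are attached as
#'   attribute `n_params` (named vector).
#' @export
run_ablation <- function(train_pairs, val_pairs, base_cfg, train_cfg,
                         variants = names(ablation_variants()), verbose = FALSE) {
  labels <- ablation_variants()
  bad <- setdiff(variants, names(labels))
  if (length(bad) > 0) {
    stop(sprintf("unknown variant label(s) %s; valid labels: %s",
                 paste(bad, collapse = ", "),
                 paste(names(labels), collapse = ", ")), call. = FALSE)
  }
  rows <- list()
  np <- integer(0)
  for (v in variants) {
    cfg <- base_cfg
    cfg$variant <- v
    fit <- train_model(cfg, train_cfg, train_pairs, val_pairs = NULL,
                       verbose = verbose)
    rows[[v]] <- evaluate_model(fit$model, val_pairs, variant = labels[[v]])
    attr(rows[[v]], "confusion") <- NULL
    np[[v]] <- n_params(fit$model)
    if (verbose) message(sprintf("%s: dice %.2f%%", labels[[v]], rows[[v]]$dice_pct))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_params") <- np
  out
}

#' Write a metrics table as CSV
#'
#' Emits the canonical metrics CSV (columns `variant`, `dice_pct`,
#' `miou_pct`, `precision_pct`, `recall_pct`).
#'
#' @param table Metrics `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  cols <- c("variant", "dice_pct", "miou_pct", "precision_pct", "recall_pct")
  utils::write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}
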