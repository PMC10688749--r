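make_micro_corpus <- function(n, seed = 1L) {
  generate_corpus(synthetic_spec(image_size = 16L, n_images = n, radius = c(3, 6),
                                 seed = seed))
}

micro_cfg <- function(variant = "lr_ccf_fc") {
  model_config(depth = 2L, base_channels = 2L, variant = variant, rank_L = 1L,
               heads_N = 1L, patch_size = 4L, embed_dim = 4L, input_size = 16L)
}

test_that("training defaults follow the published schedule", {
  tc <- train_config()
  expect_identical(tc$epochs, 40L)
  expect_identical(tc$batch_size, 4L)
  expect_equal(tc$learning_rate, 0.001)
  # Adam is the fixed optimiser: the step uses first/second moment buffers
  expect_true(all(c("m", "v", "t") %in% names(tlrseg:::adam_init(list(a = 1:3)))))
})

test_that("one epoch on four images completes with finite decreasing-capable loss", {
  corpus <- make_micro_corpus(4)
  fit <- train_model(micro_cfg(), train_config(epochs = 1L, seed = 2L), corpus)
  expect_s3_class(fit, "tlr_fit")
  expect_true(all(is.finite(fit$steps$loss)))
  expect_identical(nrow(fit$steps), 1L)  # 4 images / batch 4
  expect_error(train_model(micro_cfg(), train_config(epochs = 1L), list()),
               "empty")
})

test_that("a corrupted model aborts with a diagnostic naming the step", {
  corpus <- make_micro_corpus(4)
  model <- build_model(micro_cfg(), seed = 1L)
  model$params[["head.W"]][] <- NaN
  expect_error(train_model(model, train_config(epochs = 1L), corpus),
               "epoch 1 step 1")
})

test_that("evaluating exact oracle masks scores 100 everywhere, and misses score 0", {
  # the metric path is exercised directly from counts, independent of a model
  corpus <- make_micro_corpus(3, seed = 5L)
  pooled <- Reduce(tlrseg:::confusion_add,
                   lapply(corpus, function(p) confusion_counts(p$mask, p$mask)))
  row <- metrics_row(pooled, "oracle")
  expect_equal(unlist(row[, -1]), c(dice_pct = 100, miou_pct = 100,
                                    precision_pct = 100, recall_pct = 100))
  allbg <- Reduce(tlrseg:::confusion_add,
                  lapply(corpus, function(p) confusion_counts(p$mask * 0L, p$mask)))
  expect_equal(dice_score(allbg), 0)
})

test_that("evaluation rows match recomputation from the pooled confusion counts", {
  corpus <- make_micro_corpus(5, seed = 6L)
  model <- build_model(micro_cfg("baseline"), seed = 3L)
  row <- evaluate_model(model, corpus)
  cc <- attr(row, "confusion")
  expect_equal(row$dice_pct, dice_score(cc))
  expect_equal(row$miou_pct, miou_score(cc))
  expect_equal(row$precision_pct, precision_score(cc))
  expect_equal(row$recall_pct, recall_score(cc))
  # macro averaging stays within [0, 100] too
  mrow <- evaluate_model(model, corpus, average = "macro")
  expect_true(all(unlist(mrow[, -1]) >= 0 & unlist(mrow[, -1]) <= 100, na.rm = TRUE))
})

test_that("the ablation harness emits five labelled rows and rejects unknown variants", {
  corpus <- make_micro_corpus(6, seed = 7L)
  tab <- run_ablation(corpus[1:4], corpus[5:6], micro_cfg(),
                      train_config(epochs = 1L, seed = 4L))
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$variant, unname(ablation_variants()))
  np <- attr(tab, "n_params")
  expect_lt(np[["baseline"]], np[["ccf_fc"]])
  expect_lt(np[["ccf_fc"]], np[["lr_ccf_fc"]])
  expect_error(run_ablation(corpus[1:4], corpus[5:6], micro_cfg(),
                            train_config(epochs = 1L), variants = c("baseline", "frob")),
               "valid labels")
})

test_that("fixed seeds reproduce training histories exactly", {
  corpus <- make_micro_corpus(4, seed = 8L)
  tc <- train_config(epochs = 2L, seed = 9L)
  f1 <- train_model(micro_cfg("baseline"), tc, corpus, val_pairs = corpus[1:2])
  f2 <- train_model(micro_cfg("baseline"), tc, corpus, val_pairs = corpus[1:2])
  expect_identical(f1$steps, f2$steps)
  expect_identical(f1$epochs, f2$epochs)
})

test_that("checkpoint -> reload -> evaluate is idempotent", {
  corpus <- make_micro_corpus(4, seed = 10L)
  fit <- train_model(micro_cfg("baseline"), train_config(epochs = 1L, seed = 1L), corpus)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  back <- load_checkpoint(path)
  expect_equal(evaluate_model(back, corpus), evaluate_model(fit$model, corpus),
               tolerance = 1e-12)
})

test_that("the CLI round-trips synth -> train -> eval -> ablate", {
  dir <- file.path(tempdir(), "tlr-cli-test")
  unlink(dir, recursive = TRUE)
  dir.create(dir, recursive = TRUE)
  cfgfile <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(
    model = list(depth = 2L, base_channels = 2L, variant = "lr_ccf_fc", rank_L = 1L,
                 heads_N = 1L, patch_size = 4L, embed_dim = 4L, input_size = 16L),
    train = list(epochs = 1L, batch_size = 4L, seed = 1L),
    synth = list(image_size = 16L, n_images = 10L, radius = c(3, 6), seed = 2L)
  ), cfgfile)
  corpus_dir <- file.path(dir, "corpus")
  tlr_cli(c("synth", "--config", cfgfile, "--out", corpus_dir))
  expect_true(file.exists(file.path(corpus_dir, "manifest.tsv")))
  run_dir <- file.path(dir, "run")
  suppressMessages(tlr_cli(c("train", "--config", cfgfile, "--data", corpus_dir,
                             "--out", run_dir)))
  expect_true(file.exists(file.path(run_dir, "checkpoint.rds")))
  row <- tlr_cli(c("eval", "--checkpoint", file.path(run_dir, "checkpoint.rds"),
                   "--data", corpus_dir, "--split", "val"))
  expect_true(is.data.frame(row))
  expect_error(tlr_cli(c("frobnicate")), "unknown subcommand")
  unlink(dir, recursive = TRUE)
})
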