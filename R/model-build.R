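# Parameter construction.  Parameters live in a flat named list; the name
# prefix (enc./dec./head./ccf./fc./lr.) identifies the owning submodule and
# drives the parameter-count accounting used by the ablation checks.

#' Build a segmentation model
#'
#' Allocates and initialises all parameters of the configured variant.
#' Convolutions use He-uniform initialisation; batch-norm scales start at 1.
#'
#' @param config A [model_config()].
#' @param seed Integer seed making the initialisation reproducible.
#' @return An object of class `tlr_model`: a list with elements `config`,
#'   `params` (named list of arrays) and `state` (batch-norm running
#'   statistics).
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "tlr_model_config"))
  with_seed(seed, {
    p <- list()
    s <- list()
    ch <- cfg_channels(config)
    cb <- cfg_bott_channels(config)
    E <- config$embed_dim
    d <- config$depth

    add_conv3 <- function(name, cin, cout) {
      p[[paste0(name, ".W")]] <<- he_uniform(c(cout, cin, 9L), cin * 9L)
      p[[paste0(name, ".b")]] <<- numeric(cout)
    }
    add_bn <- function(name, c) {
      p[[paste0(name, ".gamma")]] <<- rep(1, c)
      p[[paste0(name, ".beta")]] <<- numeric(c)
      s[[paste0(name, ".rmean")]] <<- numeric(c)
      s[[paste0(name, ".rvar")]] <<- rep(1, c)
    }
    add_dconv <- function(name, cin, cout) {
      add_conv3(paste0(name, ".conv1"), cin, cout)
      add_bn(paste0(name, ".bn1"), cout)
      add_conv3(paste0(name, ".conv2"), cout, cout)
      add_bn(paste0(name, ".bn2"), cout)
    }
    add_linear <- function(name, cin, cout) {
      p[[paste0(name, ".W")]] <<- he_uniform(c(cout, cin), cin)
      p[[paste0(name, ".b")]] <<- numeric(cout)
    }

    # encoder
    cin <- config$in_channels
    for (i in seq_len(d)) {
      add_dconv(sprintf("enc.s%d", i), cin, ch[i])
      cin <- ch[i]
    }
    add_dconv("enc.bott", ch[d], cb)

    # decoder
    for (i in rev(seq_len(d))) {
      cab <- if (i == d) cb else ch[i + 1L]
      if (config$upsample == "transposed") {
        p[[sprintf("dec.s%d.up.W", i)]] <- he_uniform(c(ch[i], cab, 4L), cab * 4L)
      } else {
        p[[sprintf("dec.s%d.up.W", i)]] <- he_uniform(c(ch[i], cab), cab)
      }
      p[[sprintf("dec.s%d.up.b", i)]] <- numeric(ch[i])
      add_dconv(sprintf("dec.s%d", i), 2L * ch[i], ch[i])
    }
    add_linear("head", ch[1L], config$out_classes)

    if (cfg_has_ccf(config)) {
      ps <- cfg_patch_sizes(config)
      for (i in seq_len(d)) {
        pd <- ch[i] * ps[i]^2L
        add_linear(sprintf("ccf.emb.s%d", i), pd, E)
        add_linear(sprintf("ccf.lp.s%d.fc1", i), E, 4L * E)
        add_linear(sprintf("ccf.lp.s%d.fc2", i), 4L * E, E)
        add_linear(sprintf("ccf.unemb.s%d", i), E, pd)
      }
      for (dd in c("h", "w", "c")) for (h in seq_len(config$heads_N)) {
        for (w in c("Wq", "Wk", "Wv")) {
          p[[sprintf("ccf.attn.%s.%d.%s", dd, h, w)]] <- he_uniform(c(E, E), E)
        }
      }
    }

    if (cfg_has_lr(config)) {
      hs <- cfg_stage_sizes(config)
      for (i in seq_len(d)) {
        axes <- c(h = hs[i], w = hs[i], c = ch[i])
        for (dd in c("h", "w", "c")) {
          for (l in seq_len(config$rank_L)) {
            p[[sprintf("lr.s%d.%s.k%d", i, dd, l)]] <- stats::runif(3L, -sqrt(2), sqrt(2))
            p[[sprintf("lr.s%d.%s.kb%d", i, dd, l)]] <- 0
          }
          p[[sprintf("lr.s%d.%s.P", i, dd)]] <- he_uniform(c(E, axes[[dd]]), axes[[dd]])
        }
      }
    }

    if (cfg_has_fc(config)) {
      for (i in seq_len(d)) {
        add_conv3(sprintf("fc.s%d.align", i), ch[i], ch[i])
        add_linear(sprintf("fc.s%d.lin1", i), ch[i], ch[i])
        add_linear(sprintf("fc.s%d.lin2", i), ch[i], ch[i])
      }
    }

    structure(list(config = config, params = p, state = s), class = "tlr_model")
  })
}

#' Count model parameters
#'
#' @param model A `tlr_model`.
#' @param submodule Optional prefix restricting the count to one submodule:
#'   one of `"enc"`, `"dec"`, `"head"`, `"ccf"`, `"fc"`, `"lr"`.
#' @return Integer number of scalar parameters.
#' @export
n_params <- function(model, submodule = NULL) {
  p <- model$params
  if (!is.null(submodule)) {
    p <- p[startsWith(names(p), paste0(submodule, "."))]
  }
  sum(vapply(p, length, integer(1)))
}

#' @export
print.tlr_model <- function(x, ...) {
  cat(sprintf("<tlr_model> %s, %s parameters (enc %s, dec %s, ccf %s, fc %s, lr %s)\n",
              x$config$variant, format(n_params(x), big.mark = ","),
              format(n_params(x, "enc"), big.mark = ","),
              format(n_params(x, "dec"), big.mark = ","),
              format(n_params(x, "ccf"), big.mark = ","),
              format(n_params(x, "fc"), big.mark = ","),
              format(n_params(x, "lr"), big.mark = ",")))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Weights and batch-norm state are written in R's native serialisation
#' format with a JSON sidecar (`<path>.json`) recording the architecture
#' configuration, so a checkpoint is self-describing.
#'
#' @param model A `tlr_model`.
#' @param path File path for the checkpoint (conventionally `.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `tlr_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(params = model$params, state = model$state), path)
  cfg <- unclass(model$config)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  blob <- readRDS(path)
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- model_config(depth = cfg$depth, base_channels = cfg$base_channels,
                         variant = cfg$variant, rank_L = cfg$rank_L,
                         heads_N = cfg$heads_N, patch_size = cfg$patch_size,
                         out_classes = cfg$out_classes, embed_dim = cfg$embed_dim,
                         in_channels = cfg$in_channels, input_size = cfg$input_size,
                         upsample = cfg$upsample, fc_mode = cfg$fc_mode)
  structure(list(config = config, params = blob$params, state = blob$state),
            class = "tlr_model")
}
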