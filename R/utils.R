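# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dim <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

# local RNG scope: run expr with a private seed without disturbing the
# caller's .Random.seed
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive independent sub-seeds from a master seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# feature maps travel internally as C x (B*H*W) matrices, columns sample-major
# with column-major (row-fastest) pixel order inside each sample
as_chw <- function(m, H, W) {
  # C x HW matrix -> (C,H,W) array
  array(m, dim = c(nrow(m), H, W))
}
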