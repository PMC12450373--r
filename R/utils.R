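# Internal helpers shared across modules.

# Run `expr` under set.seed(seed) without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(abs(seed) %% 2147483647))
  expr
}

# Numerically stable log(sum(exp(x))) along rows of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Row-wise softmax, stabilized.
row_softmax <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

stop_if_not_scalar_prob <- function(x, name, open_left = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && x <= 1 &&
    (if (open_left) x > 0 else x >= 0)
  if (!ok) stop(sprintf("'%s' must be a probability in %s0, 1]",
                        name, if (open_left) "(" else "["))
  invisible(x)
}
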