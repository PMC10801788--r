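# Internal utilities: error signalling, seeded evaluation, deterministic matmul.

stop_jgrs <- function(message, class) {
  stop(structure(
    class = c(class, "jgrs_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards. A `NULL` seed evaluates `code` in the current stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Independent child seeds derived from one master seed (kept < 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(2147483646L, n)))
}

# Matrix product with a fixed left-to-right accumulation order.
#
# colSums() accumulates sequentially over rows of its argument, so the partial
# sums of `t(a) * b[, j]` are reproduced exactly when rows whose weights are
# exactly zero are dropped. The bitwise surgery identity relies on this; BLAS
# %*% reassociates sums and does not provide it.
det_matmul <- function(a, b) {
  ta <- t(a)
  out <- matrix(0, nrow(a), ncol(b))
  for (j in seq_len(ncol(b))) {
    out[, j] <- colSums(ta * b[, j])
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
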