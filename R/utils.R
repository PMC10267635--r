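#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so seeded package internals never disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic stream of sub-seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise cross product for 3-vectors (x, y: n x 3 or length-3).
cross3 <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (is.null(dim(y))) y <- matrix(y, 1L)
  if (nrow(x) == 1L && nrow(y) > 1L) x <- x[rep(1L, nrow(y)), , drop = FALSE]
  if (nrow(y) == 1L && nrow(x) > 1L) y <- y[rep(1L, nrow(x)), , drop = FALSE]
  cbind(x[, 2L] * y[, 3L] - x[, 3L] * y[, 2L],
        x[, 3L] * y[, 1L] - x[, 1L] * y[, 3L],
        x[, 1L] * y[, 2L] - x[, 2L] * y[, 1L])
}

vnorm <- function(x) {
  if (is.null(dim(x))) sqrt(sum(x^2)) else sqrt(rowSums(x^2))
}

unit <- function(x) {
  if (is.null(dim(x))) x / vnorm(x) else x / vnorm(x)
}
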