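#' Weighted mean
#'
#' @param x numeric vector.
#' @param w positive weights, recycled if length 1.
#' @return `sum(w * x) / sum(w)`.
#' @keywords internal
wmean <- function(x, w) {
  if (length(w) == 1L) w <- rep(w, length(x))
  stopifnot(length(x) == length(w))
  sum(w * x) / sum(w)
}

#' Kish effective sample size
#'
#' \eqn{(\sum w)^2 / \sum w^2}; equals n under equal weights and shrinks as
#' weights become unequal.
#'
#' @param w positive weights.
#' @return effective sample size (real).
#' @export
kish_eff_n <- function(w) {
  if (any(w <= 0)) stop("weights must be positive")
  sum(w)^2 / sum(w^2)
}

# Run an expression under a locally seeded RNG, restoring the caller's
# RNG state afterwards so package functions never clobber the session seed.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Independent per-replication seeds derived from one master seed.
derive_substream_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
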