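#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded at `seed`,
#' restoring the previous RNG state afterwards, so that seeded calls are
#' reproducible without disturbing the caller's random stream. With
#' `seed = NULL` the expression is evaluated with the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a hierarchy of independent stream seeds from a master seed
#'
#' Replicate-level seeds are drawn once from the master seed, so growing the
#' number of replicates later does not perturb the seeds of earlier ones
#' (seed i is always the i-th draw from the master stream).
#'
#' @param seed Master integer seed, or `NULL` for unseeded draws.
#' @param n Number of derived seeds.
#' @return Integer vector of length `n`, each usable as a `seed` argument.
#' @examples
#' derive_seeds(1, 3)
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(n >= 1)
  with_seed_(seed, sample.int(2147483647L, n))
}
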