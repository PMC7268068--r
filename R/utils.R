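# Internal helpers: seeded evaluation and deterministic child-seed derivation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded package functions do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive independent child seeds from a master seed
#'
#' Any stage of the pipeline can be rerun in isolation by regenerating its
#' child seed from the master seed, so per-participant and per-stage
#' randomness is reproducible without sharing one RNG stream.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' spawn_seeds(42, 3)
spawn_seeds <- function(seed, n) {
  stopifnot(n >= 1)
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# stopifnot() with a custom message prefix for parameter validation
check_param <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
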