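# Seeded sub-stream helpers. All exported stochastic operations take one
# explicit integer seed; internal stages derive child seeds deterministically
# so that no call touches the caller's global RNG state.

#' Derive a child seed from a parent seed and integer keys
#'
#' Deterministic counter-based splitting: the same `(seed, keys)` always maps
#' to the same child seed, and distinct key paths give (for practical
#' purposes) independent streams. Used so that every stage of a pipeline run
#' draws from its own stream while the whole run is reproducible from one
#' integer.
#'
#' @param seed integer parent seed.
#' @param ... one or more integer keys identifying the sub-stream.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' split_seed(1L, 1L) != split_seed(1L, 2L)
split_seed <- function(seed, ...) {
  keys <- c(...)
  stopifnot(length(keys) >= 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in keys) {
    # multiplier 69069 keeps h * mult + k well inside double precision
    h <- (h * 69069 + (as.numeric(k) %% m) + 1) %% m
    h <- (h * 69069 + 12345) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
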