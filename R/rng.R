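# Seeded-stream helpers. Every stochastic operation takes an explicit `seed`
# and evaluates under a locally set RNG state, restoring the caller's state on
# exit, so stages can be re-run in isolation and runs are reproducible from a
# single root seed.

local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

#' Derive an independent sub-stream seed
#'
#' Hashes a stage key together with the root seed so each pipeline stage
#' draws from its own reproducible stream (kept below 2^31).
#'
#' @param seed integer root seed.
#' @param key character stage key.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 13) %% 2147483647)
}
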