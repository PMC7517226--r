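# Seed plumbing. Every stochastic operation in the package draws its
# randomness from a seed derived deterministically from one user-supplied
# integer plus a context (strings/integers naming the operation), so whole
# experiments replay bit-identically from a single seed and individual
# machines can be re-derived in isolation.

#' Derive a child seed from a parent seed and a context
#'
#' Folds the context arguments (strings or numbers) into the parent seed with
#' a multiplicative-congruential hash. The result is a stable, non-negative
#' 31-bit integer: the same `(seed, ...)` always yields the same child seed,
#' across sessions and platforms.
#'
#' @param seed Parent integer seed.
#' @param ... Context: character or numeric scalars/vectors naming the
#'   operation (e.g. `"machine", 3`).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "machine", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- abs(as.double(seed)) %% 2147483647
  for (part in list(...)) {
    vals <- if (is.character(part)) {
      utf8ToInt(paste(part, collapse = "\r"))
    } else {
      as.double(part)
    }
    for (v in vals) {
      # 69069: classic Marsaglia multiplier; arithmetic stays < 2^53
      h <- (h * 69069 + abs(v) + 13) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Seeded fair coin returning 0 or 1; used for all mode tie-breaks.
coin_flip <- function(tie_seed, ...) {
  with_seed(derive_seed(tie_seed, "coin", ...), sample(0:1, 1L))
}
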