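# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
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
  force(code)
}

# seed must be a single finite integerish value (R integers are 32-bit).
check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed) ||
      seed != trunc(seed) || abs(seed) >= 2^31) {
    stop("`seed` must be a single integer with |seed| < 2^31", call. = FALSE)
  }
  as.integer(seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
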