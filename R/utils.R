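# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library functions taking a `seed` argument
# never disturb the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: all pipeline randomness flows from one
# config seed through named substreams. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_square_matrix <- function(m) {
  is.matrix(m) && nrow(m) == ncol(m)
}
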