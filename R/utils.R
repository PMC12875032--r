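# Internal helpers shared across the pipeline stages.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed derivation (MINSTD-style), kept below 2^31 - 1 so the
# result is always a valid integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483647)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Half-up rounding to integers (base round() is half-even).
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}
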