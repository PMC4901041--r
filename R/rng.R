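# Internal RNG discipline: every function that consumes randomness takes an
# explicit seed, runs in its own stream, and restores the caller's RNG state.

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

with_seed <- function(seed, code) {
  with_preserved_rng({
    set.seed(seed)
    force(code)
  })
}

# Deterministic per-plasmid sub-stream seed. Keeps draws for plasmid i fixed
# as n_plasmids grows, so enlarging a sample extends it instead of
# reshuffling it. The multiplier is the 32-bit Knuth hash constant; all
# arithmetic stays below 2^53 so it is exact in doubles.
derive_stream_seed <- function(seed, index) {
  (abs(seed) %% 2147483647 + index * 2654435761) %% 2147483647
}
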