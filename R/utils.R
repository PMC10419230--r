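# internal helpers

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic entry points route
# their randomness through this so that a seed argument fully determines
# the output without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  expr
}

# derive a distinct 31-bit sub-seed from a base seed and a stream index
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
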