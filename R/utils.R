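# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All randomness in the package funnels through this so
# that simulations are reproducible without clobbering the user's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# derive a reproducible sub-seed from a master seed and a stream index,
# staying inside 32-bit integer range
sub_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647
}
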