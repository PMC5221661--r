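# Small internal helpers.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps every generator a pure function of
# (arguments, seed).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required (no silent default entropy)")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
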