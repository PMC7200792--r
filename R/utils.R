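# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive `n` independent sub-seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Rescale a matrix linearly onto [lo, hi]; constant input maps to lo.
rescale_range <- function(x, lo, hi) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(matrix(lo, nrow(x), ncol(x)))
  (x - r[1]) / (r[2] - r[1]) * (hi - lo) + lo
}

`%||%` <- function(a, b) if (is.null(a)) b else a
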