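# Internal helpers: seeded evaluation and derived seeds.

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based derivation of per-unit seeds from a master seed, so that
# per-searchlight / per-participant randomness is reproducible regardless of
# evaluation order. Linear-congruential mix kept inside 32-bit integer range.
deriveSeed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 +
                as.numeric(counter) * 16807) %% 2147483629 + 1)
}

# Pearson correlation of two vectors plus the gradient of r with respect to x.
# Used by the synthesis backward pass; the gradient is mean-zero by
# construction (r is shift-invariant).
corrGradX <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc * xc); syy <- sum(yc * yc)
  if (sxx <= 0 || syy <= 0)
    stop("degenerate input: zero-variance vector in correlation gradient")
  sxy <- sum(xc * yc)
  den <- sqrt(sxx * syy)
  list(r = sxy / den, grad = (yc - (sxy / sxx) * xc) / den)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
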