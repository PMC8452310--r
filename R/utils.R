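# Internal helpers: seeded evaluation, seed splitting, phase unwrapping.

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Deterministic seed-splitting scheme: substream k of master seed s is
# (s * 1009 + k) mod (2^31 - 1). All stochastic stages of the generator and
# the permutation null draw from substreams so that stages stay reproducible
# independently of call order.
splitSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

# Unwrap a phase sequence (radians): remove 2*pi jumps.
unwrapPhase <- function(p) {
  if (length(p) < 2L) return(p)
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

# Parabolic (three-point) refinement of an extremum located at sample i of y;
# returns fractional sample offset in (-0.5, 0.5).
parabolicOffset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  max(min(off, 0.5), -0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
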