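# Small internal helpers shared across modules.

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Half-away-from-zero integer rounding (base round() is banker's).
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

# 0-based position -> bin index (0-based)
binIndex0 <- function(pos0, binSize) floor(pos0 / binSize)
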