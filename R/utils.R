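#' @importFrom stats approx
NULL

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic fan-out of one global seed into per-stage seeds (kept
## below 2^31).  Documented in the methods vignette.
.stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 + stage * 7919) %% 2147483647)
}

## Root-mean-square error between two numeric arrays.
.rmse <- function(a, b) sqrt(mean((a - b)^2))
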