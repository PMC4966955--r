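`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `code` under a temporary RNG state so generators are pure
## functions of their seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stage-specific sub-seed from a master seed, kept < 2^31.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  ## double arithmetic: products can exceed .Machine$integer.max
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %% 2147483647)
}
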