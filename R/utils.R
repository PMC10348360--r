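## small shared helpers

## evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## derive a stream of child seeds from a master seed (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 11 * as.double(k) + 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
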