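# Run code with a temporarily-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a deterministic 31-bit substream seed from (master, id)
substream_seed <- function(seed, id) {
  (as.numeric(seed) * 1000003 + 7919 * as.numeric(id)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
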