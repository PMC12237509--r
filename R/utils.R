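# run code under a fixed RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
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

# derive a stage seed from a master seed; keeps results below 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(preprocess = 11L, coaccess = 23L, consensus = 37L,
               superenhancers = 53L, markers = 71L, simulate = 89L,
               shuffle = 97L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
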