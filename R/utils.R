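# Run code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-component substream seed, kept inside 32-bit range so
# adding a submodel never perturbs another's draws.
substream_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) * 1009 + 97 * index) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
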