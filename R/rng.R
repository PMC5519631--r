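# ---- seed plumbing ---------------------------------------------------------
#
# Every source of randomness flows from one integer seed. Stage- or
# operation-level substreams are derived deterministically from (seed, name)
# so a stage can be re-run in isolation and reproduce its draws.

# run expr under a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named substream seed
#'
#' Deterministic 31-bit hash of (seed, name); used to key per-stage random
#' streams off one global seed.
#'
#' @param seed integer master seed
#' @param name character stream name
#' @return integer seed in `[0, 2^31 - 1)`
#' @export
substream_seed <- function(seed, name) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}
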