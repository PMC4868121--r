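# Named random substreams: every stochastic stage derives its own integer
# seed from (master seed, stream name), so stages can be re-run
# independently yet reproducibly.

.SUBSTREAM_MOD <- 2147480009  # prime below 2^31

#' Derive a substream seed
#'
#' Deterministically maps a master seed and a stream name to an integer
#' seed below 2^31, so that independent pipeline stages draw from
#' independent, reproducible streams.
#'
#' @param seed Integer master seed.
#' @param name Stream name (character scalar).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% .SUBSTREAM_MOD
  as.integer((h + (seed %% .SUBSTREAM_MOD) * 48271) %% .SUBSTREAM_MOD)
}

# Evaluate code under a given seed, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
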