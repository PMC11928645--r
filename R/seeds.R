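#' Derive a named substream seed from a master seed
#'
#' All stochastic stages draw their seed from one master seed plus a stream
#' name, so any stage can be re-run in isolation and still reproduce the
#' draws it made inside a full pipeline run.
#'
#' @param master Integer master seed.
#' @param stream Character stream name (e.g. `"trials"`, `"spikes"`, `"agent"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @examples
#' substream_seed(1, "trials")
#' @export
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stream), length(stream) == 1L, nzchar(stream))
  h <- 0
  for (cp in utf8ToInt(stream)) h <- (h * 31 + cp) %% 2147483629
  as.integer((abs(as.numeric(master)) + h * 97) %% 2147483629)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards so package functions never clobber global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
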