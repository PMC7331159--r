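## Seed fan-out: one global seed deterministically derives independent
## substream seeds per generator, so composite scenarios (shoulder + gait +
## volume + phantom) are reproducible from a single integer.

#' Derive a substream seed from a global seed and a stream label
#'
#' A small string hash keeps substreams decoupled; the result is always a
#' valid 31-bit non-negative integer.
#'
#' @param seed global integer seed.
#' @param label character stream label (e.g. `"shoulder"`, `"gait"`).
#' @return integer seed for the substream.
#' @export
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
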