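#' Derive a stage seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so each pipeline stage is reproducible in isolation: rerunning
#' a single stage with the manifest's master seed gives the same draws no
#' matter which other stages ran before it.
#'
#' @param seed Master integer seed.
#' @param stream Character name of the substream (e.g. `"simulate"`,
#'   `"rarefy"`, `"null_model"`).
#' @return An integer seed, always in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(42, "rarefy")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # small multiplicative hash of the stream name, folded into 31 bits
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
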