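# Internal helpers.

#' Derive a named substream seed
#'
#' All randomness in the package flows from one top-level seed through
#' named substreams, so each pipeline stage is individually reproducible.
#' The derived value is a deterministic 31-bit hash of the seed and the
#' stream name.
#'
#' @param seed Integer top-level seed.
#' @param name Character stream name.
#' @return Integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (k in utf8ToInt(name)) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h)
}

# run code under a derived substream seed
.with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
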