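#' Derive a named RNG stream seed from a master seed
#'
#' All randomness in the package flows through named streams (grid
#' assignment, connectivity, weights, dynamics, stimulus encoding,
#' analysis resampling) derived deterministically from one master seed, so
#' that e.g. network wiring is reproducible independently of how many
#' stimuli were encoded before building it.
#'
#' @param master master seed (integer)
#' @param stream stream name (character scalar)
#' @return a positive integer seed below 2^31
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.character(stream), length(stream) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  s <- (as.double(master) * 48271 + h * 16807) %% 2147483563
  as.integer(s) + 1L
}
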