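# Small shared helpers.

#' Derive a bounded integer sub-seed
#'
#' Deterministic hash of a base seed and two indices, kept below 2^31 so
#' it is always a valid R integer seed. Used to give every simulated
#' sample, arm and recursion node an independent, reproducible stream.
#'
#' @param seed base integer seed.
#' @param a,b non-negative integer indices.
#' @return Integer seed.
#' @export
subSeed <- function(seed, a, b = 0L) .nodeSeed(seed, a, b)
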