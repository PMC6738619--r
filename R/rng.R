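#' Derive a reproducible substream seed
#'
#' Deterministic integer mixing of a master seed, a stream label and a
#' replicate index. Replicate `r` gets the same substream seed for every
#' sweep value, so sweeps share common random numbers across parameter
#' values. All arithmetic stays below 2^53, so the result is exact in
#' doubles, and the returned seed is below 2^31.
#'
#' @param master Master integer seed.
#' @param stream Small non-negative integer distinguishing independent uses
#'   (e.g. 1 = MTF sweep, 2 = SF sweep).
#' @param index Replicate index (>= 1).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream = 0L, index = 1L) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(master) %% m) * 1000003 + as.numeric(stream) * 10007 +
    as.numeric(index)
  as.integer(s %% m)
}
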