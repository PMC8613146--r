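#' Derive a reproducible child seed
#'
#' Folds a base seed and any number of integer indices (step index,
#' repetition index, stream tag, ...) into a single seed below 2^31
#' using a MINSTD-style multiplicative rolling hash. Every source of
#' randomness in a scan draws its seed through this function, so
#' results are reproducible from the base seed alone and independent of
#' execution order.
#'
#' @param base integer base seed.
#' @param ... further non-negative integer indices.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(base, ...) {
  ks <- c(base, ...)
  m <- 2147483647  # 2^31 - 1
  s <- 0
  for (k in ks) {
    s <- (s * 48271 + (abs(as.numeric(k)) %% m) + 1) %% m
  }
  as.integer(s)
}
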