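#' Derive a child seed from a master seed
#'
#' Deterministic 32-bit integer mixing used to give every sample (and every
#' regeneration attempt) its own reproducible random stream. The scheme is a
#' small multiplicative hash; children of distinct (seed, index) pairs are
#' distinct with overwhelming probability and always fall in \[1, 2^31 - 2\].
#'
#' @param master Integer master seed.
#' @param index Integer index (sample number, attempt number, ...).
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- (as.numeric(master) %% m) * 48271 %% m
  h <- (h + as.numeric(index) * 16807 + 12345) %% m
  h <- (h * 69621) %% m
  as.integer(if (h < 1) 1 else h)
}

# round half away from zero (commercial rounding); base round() rounds half
# to even, which would map 2.5 -> 2
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
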