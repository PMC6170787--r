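#' Derive a reproducible child seed from a master seed
#'
#' Experiments fan a single master seed out to per-(subject, segment,
#' surrogate) child seeds so that runs are bitwise reproducible regardless of
#' evaluation order. The derivation is a small multiplicative hash over the
#' index path, kept strictly below 2^31 so the result is a valid R integer
#' seed.
#'
#' @param master Integer master seed.
#' @param ... Non-negative integer indices identifying the consumer
#'   (e.g. subject, segment, surrogate draw).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, 3, 7) != derive_seed(1, 7, 3)
#' @export
derive_seed <- function(master, ...) {
  idx <- c(as.numeric(master), vapply(list(...), as.numeric, numeric(1)))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 17
  for (v in idx) {
    # multipliers < 2^17 keep every product < 2^48: exact in double precision
    h <- ((h * 48271) %% m + (abs(v) %% m) * 12345) %% m
    h <- (h * 69069 + 1) %% m
  }
  as.integer(h)
}
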