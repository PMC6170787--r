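#' Fourier phase-randomized surrogate of a segment
#'
#' Applies the discrete Fourier transform per channel, rotates the phase of
#' every positive-frequency bin by an independent uniform angle in (0, 2*pi),
#' enforces conjugate symmetry on the negative frequencies, and inverse
#' transforms. The DC and (for even lengths) Nyquist bins are left untouched
#' (they must stay real for a real-valued output). The surrogate therefore
#' shares the original's amplitude spectrum, periodogram, mean and variance
#' exactly; only the phase structure — where any nonlinearity lives — is
#' destroyed.
#'
#' When `x` has several columns the same rotation sequence is applied to
#' every channel (the multivariate variant), which preserves all
#' cross-spectrum phase differences and hence the linear cross-correlation
#' structure between channels.
#'
#' @param x Numeric vector, matrix (time x channel), or `segment`.
#' @param angles Optional rotation angles (one per positive-frequency bin,
#'   i.e. `floor((n-1)/2)` values). Drawn from the current RNG state when
#'   omitted. Forcing all angles to 0 returns the input exactly.
#' @return Surrogate samples with the same shape as the input.
#' @examples
#' x <- rnorm(256)
#' s <- phase_randomize(x)
#' max(abs(Mod(fft(s)) - Mod(fft(x))))  # amplitude spectrum preserved
#' @export
phase_randomize <- function(x, angles = NULL) {
  samples <- if (inherits(x, "segment")) x$samples else x
  vec <- is.vector(samples)
  if (vec) samples <- matrix(samples, ncol = 1L)
  if (anyNA(samples) || any(!is.finite(samples))) stop("input contains NA/Inf")
  n <- nrow(samples)
  if (n < 4) stop("segment too short to phase-randomize (need >= 4 samples)")
  npos <- floor((n - 1) / 2)         # bins 2 .. npos+1 (excludes DC/Nyquist)
  if (is.null(angles)) angles <- runif(npos, 0, 2 * pi)
  if (length(angles) != npos)
    stop("`angles` must have length ", npos)
  rot <- exp(1i * angles)
  out <- samples
  for (j in seq_len(ncol(samples))) {
    X <- fft(samples[, j])
    X[2:(npos + 1)] <- X[2:(npos + 1)] * rot
    # conjugate symmetry for the negative frequencies; DC/Nyquist untouched
    X[n:(n - npos + 1)] <- Conj(X[2:(npos + 1)])
    out[, j] <- Re(fft(X, inverse = TRUE)) / n
  }
  if (vec) out[, 1] else out
}

#' @rdname phase_randomize
#' @param ... Passed on to [phase_randomize()].
#' @export
phase_randomize_multivariate <- function(x, ...) {
  samples <- if (inherits(x, "segment")) x$samples else x
  if (is.vector(samples) || ncol(samples) < 2)
    stop("multivariate phase randomization needs >= 2 channels")
  phase_randomize(x, ...)
}

#' Build a surrogate ensemble for a segment
#'
#' Draws `n` independent phase-randomized surrogates of the segment from a
#' seeded generator. Each multichannel surrogate uses one shared rotation
#' sequence across its channels.
#'
#' @param segment A `segment`, numeric vector, or matrix.
#' @param n Number of surrogates (default 20; must be >= 2 so the surrogate
#'   standard deviation in the z-test is defined).
#' @param seed Integer seed making the ensemble reproducible.
#' @return An object of class `surrogate_ensemble`: list with `original`,
#'   `surrogates` (list of n arrays), `n_surrogates`, `seed`.
#' @export
build_ensemble <- function(segment, n = 20, seed = 1L) {
  if (n < 2) stop("need at least 2 surrogates (std undefined otherwise)")
  set.seed(as.integer(seed))
  surr <- vector("list", n)
  for (i in seq_len(n)) surr[[i]] <- phase_randomize(segment)
  structure(list(original = segment, surrogates = surr,
                 n_surrogates = as.integer(n), seed = as.integer(seed)),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  os <- if (inherits(x$original, "segment")) x$original$samples else x$original
  if (is.vector(os)) os <- matrix(os, ncol = 1)
  cat(sprintf("<surrogate_ensemble> %d surrogates of a %d x %d segment (seed %d)\n",
              x$n_surrogates, nrow(os), ncol(os), x$seed))
  invisible(x)
}
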