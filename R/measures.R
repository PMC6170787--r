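# The five nonlinear discriminating statistics. All are deterministic pure
# functions of their input; degenerate inputs return NA_real_ with a warning
# so the z-test layer can exclude and log them.

#' Higuchi fractal dimension
#'
#' Time-domain curve-length estimate of the fractal dimension: for each delay
#' `k = 1..k_max` the normalized curve length `L(k)` (averaged over the `k`
#' possible offsets) scales as `k^-D`; `D` is the negative slope of an
#' ordinary least-squares fit of `ln L(k)` on `ln k`. Roughly 1 for smooth
#' curves and 2 for uncorrelated noise.
#'
#' @param x Numeric vector (length >= 10 * k_max recommended).
#' @param k_max Maximum delay (default 8).
#' @return The fractal dimension, or `NA` for a constant (degenerate) series.
#' @examples
#' higuchi_fd(seq_len(1000))   # a straight line: exactly 1
#' @export
higuchi_fd <- function(x, k_max = 8) {
  x <- as.numeric(x)
  if (k_max < 2) stop("k_max must be >= 2")
  if (length(x) < 2 * k_max) stop("series too short for k_max = ", k_max)
  if (anyNA(x) || any(!is.finite(x))) stop("input contains NA/Inf")
  L <- higuchi_lengths_cpp(x, as.integer(k_max))
  if (any(L <= 0) || anyNA(L)) {
    warning("degenerate series: curve length vanishes; returning NA")
    return(NA_real_)
  }
  k <- seq_len(k_max)
  -unname(coef(lm(log(L) ~ log(k)))[2])
}

#' Katz fractal dimension
#'
#' Treats the series as a planar curve with unit abscissa steps. With total
#' curve length `L` (sum of successive Euclidean point distances), diameter
#' `d` (maximum distance from the first point) and `n = N - 1` steps:
#' `KFD = log10(n) / (log10(n) + log10(d / L))`. Equal to 1 for any strictly
#' monotone line.
#'
#' @param x Numeric vector, length >= 3.
#' @return The fractal dimension, or `NA` for a constant series.
#' @export
katz_fd <- function(x) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 3) stop("need at least 3 samples")
  if (anyNA(x) || any(!is.finite(x))) stop("input contains NA/Inf")
  dx <- diff(x)
  L <- sum(sqrt(1 + dx^2))
  d <- max(sqrt((seq_len(N) - 1)^2 + (x - x[1])^2))
  if (d == 0 || L == 0) {
    warning("degenerate series for Katz dimension; returning NA")
    return(NA_real_)
  }
  n <- N - 1
  log10(n) / (log10(n) + log10(d / L))
}

#' Lempel–Ziv complexity of a median-binarized series
#'
#' Binarizes the series at its median (symbol 1 for values strictly above,
#' 0 otherwise — ties go to 0), then counts the phrases of the exhaustive
#' production history with the Kaspar–Schuster sequential algorithm. Both the
#' raw phrase count `c` and the normalized complexity `c * log2(n) / n` are
#' returned; within a fixed segment length they are monotone in each other,
#' so the surrogate z-test is unaffected by the choice.
#'
#' @param x Numeric vector (length >= 2), or an integer 0/1 vector taken as
#'   an already-binarized sequence.
#' @param binarize Set `FALSE` to treat `x` as a symbol sequence directly.
#' @return List with `count`, `normalized`, and `n`.
#' @export
lempel_ziv_complexity <- function(x, binarize = TRUE) {
  if (length(x) < 2) stop("need at least 2 samples")
  if (anyNA(x)) stop("input contains NA")
  s <- if (binarize) as.integer(x > median(x)) else as.integer(x)
  cnt <- lzc_count_cpp(s)
  n <- length(s)
  list(count = cnt, normalized = cnt * log2(n) / n, n = n)
}

#' Sample entropy
#'
#' Negative natural logarithm of the conditional probability that two
#' template sequences matching for `m` points (Chebyshev distance <= `r`,
#' self-matches excluded) still match at the next point. `r` is
#' `r_factor * sd(x)`, so the measure is invariant to affine transforms of
#' the input. Larger values mean a more irregular signal.
#'
#' @param x Numeric vector, length > m + 1.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a multiple of the sample standard deviation
#'   (default 0.2).
#' @return Sample entropy (>= 0); `NA` when no template pair matches at
#'   length `m + 1` (log of zero) or the series is constant.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stop("series too short for m = ", m)
  if (anyNA(x) || any(!is.finite(x))) stop("input contains NA/Inf")
  s <- sd(x)
  if (s == 0) {
    warning("constant series: sample entropy undefined; returning NA")
    return(NA_real_)
  }
  ab <- sampen_counts_cpp(x, as.integer(m), r_factor * s)
  if (ab[2] == 0 || ab[1] == 0) {
    warning("no matching templates within tolerance; returning NA")
    return(NA_real_)
  }
  -log(ab[1] / ab[2])
}

#' Synchronization likelihood between two series
#'
#' State-space recurrence measure of (possibly nonlinear) interdependence.
#' Both series are delay-embedded (lag `lag_L`, dimension `dim_m`); for each
#' reference time the per-series critical distance is the empirical
#' `p_ref`-quantile of the embedded distances to the admissible times `j`
#' with `w1 < |i - j| < w2` (Theiler window `w1` excludes autocorrelated
#' neighbours, `w2` bounds the horizon); the synchronization likelihood at
#' the reference time is the fraction of x-recurrences that are
#' simultaneously y-recurrences. The average over reference times is 1 for
#' identical signals and ~`p_ref` for independent ones.
#'
#' The historical parameterization for 5-s EEG segments at 1000 Hz is
#' `lag_L = 7`, `dim_m = 136`, `p_ref = 0.01`, `w1 = 2000`, `w2 = 2999`
#' (about `n_rec = 10` recurrences per reference time); tests and cohort
#' sweeps use lighter embeddings, which the z-test contract does not care
#' about.
#'
#' @param x,y Equal-length numeric vectors.
#' @param lag_L Embedding lag in samples.
#' @param dim_m Embedding dimension.
#' @param w1,w2 Inner and outer Theiler windows (samples), `w1 < w2`.
#' @param p_ref Recurrence fraction in (0, 1).
#' @return Mean synchronization likelihood in (0, 1].
#' @export
synchronization_likelihood <- function(x, y, lag_L = 7, dim_m = 136,
                                       w1 = 2000, w2 = 2999, p_ref = 0.01) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (w1 >= w2) stop("need w1 < w2")
  if (p_ref <= 0 || p_ref >= 1) stop("p_ref must be in (0, 1)")
  if (length(x) < (dim_m - 1) * lag_L + 4)
    stop("series too short for the requested embedding")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: synchronization likelihood undefined; returning NA")
    return(NA_real_)
  }
  sl_cpp(x, y, as.integer(lag_L), as.integer(dim_m),
         as.integer(w1), as.integer(w2), p_ref)
}

# measure registry used by the experiment harness ------------------------

#' Look up a measure function by name
#'
#' Returns a function `f(samples_matrix)` evaluating the named statistic on a
#' segment sample array. Univariate measures use column 1; the
#' synchronization likelihood uses columns 1 and 2.
#'
#' @param name One of `"hfd"`, `"kfd"`, `"lzc"`, `"sampen"`, `"sl"`.
#' @param sl_params Optional list overriding the reduced-default SL
#'   parameters used in cohort runs (`lag_L`, `dim_m`, `w1`, `w2`, `p_ref`).
#' @return A function of one matrix argument returning a scalar.
#' @export
measure_function <- function(name = c("hfd", "kfd", "lzc", "sampen", "sl"),
                             sl_params = NULL) {
  name <- match.arg(name)
  if (name == "sl") {
    p <- modifyList(list(lag_L = 2, dim_m = 5, w1 = 10, w2 = 160,
                         p_ref = 0.05), as.list(sl_params %||% list()))
    return(function(s) synchronization_likelihood(
      s[, 1], s[, min(2L, ncol(s))], p$lag_L, p$dim_m, p$w1, p$w2, p$p_ref))
  }
  switch(name,
    hfd = function(s) higuchi_fd(s[, 1]),
    kfd = function(s) katz_fd(s[, 1]),
    lzc = function(s) lempel_ziv_complexity(s[, 1])$normalized,
    sampen = function(s) sample_entropy(s[, 1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
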