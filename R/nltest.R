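#' Surrogate z-test for one segment
#'
#' Compares the nonlinear statistic of the original segment with the
#' distribution of the same statistic over its surrogate ensemble:
#' `z = (q_data - mean(q_surrogate)) / sd(q_surrogate)` with the sample
#' (n-1) standard deviation. The linearity null is rejected when
#' `|z| > threshold` (1.96 for the two-tailed 5% level; kept at its nominal
#' value even though 20 surrogates make the true operating level slightly
#' heavier-tailed — see the calibration test).
#'
#' Segments whose surrogate spread is zero, or whose statistic is undefined
#' on the original or any surrogate, yield an undefined-z result
#' (`z = NA`, `valid = FALSE`) which [degree_of_nonlinearity()] excludes
#' from both numerator and denominator.
#'
#' @param q_data Statistic value on the original segment.
#' @param q_surrogates Numeric vector of statistic values on >= 2 surrogates.
#' @param threshold Two-tailed rejection threshold (default 1.96).
#' @param alpha_level Nominal level, recorded in the result (default 0.05).
#' @return An object of class `nl_test_result` with fields `q_data`,
#'   `q_surr_mean`, `q_surr_std`, `z`, `rejected`, `valid`, `threshold`,
#'   `alpha_level`.
#' @examples
#' z_statistic(1.5, c(0.8, 1.0, 1.2))
#' @export
z_statistic <- function(q_data, q_surrogates, threshold = 1.96,
                        alpha_level = 0.05) {
  if (length(q_surrogates) < 2) stop("need at least 2 surrogate values")
  valid <- is.finite(q_data) && all(is.finite(q_surrogates))
  m <- if (valid) mean(q_surrogates) else NA_real_
  s <- if (valid) sd(q_surrogates) else NA_real_
  if (valid && s == 0) valid <- FALSE
  z <- if (valid) (q_data - m) / s else NA_real_
  structure(list(q_data = q_data, q_surr_mean = m, q_surr_std = s, z = z,
                 rejected = if (valid) abs(z) > threshold else NA,
                 valid = valid, threshold = threshold,
                 alpha_level = alpha_level),
            class = "nl_test_result")
}

#' @export
print.nl_test_result <- function(x, ...) {
  if (!x$valid) cat("<nl_test_result> undefined z (degenerate surrogate spread)\n")
  else cat(sprintf(
    "<nl_test_result> q = %.5g, surrogate %.5g +/- %.5g, z = %.3f -> %s\n",
    x$q_data, x$q_surr_mean, x$q_surr_std, x$z,
    if (x$rejected) "REJECT linearity" else "no rejection"))
  invisible(x)
}

#' Evaluate a measure over a surrogate ensemble and run the z-test
#'
#' @param ensemble A [build_ensemble()] result.
#' @param measure A function of one sample-matrix argument (see
#'   [measure_function()]) or a measure name.
#' @param ... Passed to [z_statistic()].
#' @return An `nl_test_result`.
#' @export
test_segment <- function(ensemble, measure, ...) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  if (is.character(measure)) measure <- measure_function(measure)
  as_mat <- function(s) {
    v <- if (inherits(s, "segment")) s$samples else s
    if (is.vector(v)) matrix(v, ncol = 1) else v
  }
  q0 <- suppressWarnings(measure(as_mat(ensemble$original)))
  qs <- vapply(ensemble$surrogates,
               function(s) suppressWarnings(measure(as_mat(s))), numeric(1))
  z_statistic(q0, qs, ...)
}

#' Degree of nonlinearity (DEG)
#'
#' Percentage of segments on which the surrogate z-test rejected the
#' linearity null. Undefined-z segments are excluded from both the count and
#' the denominator.
#'
#' @param results List of `nl_test_result` objects, or a numeric vector of z
#'   values (NA = undefined).
#' @param threshold Rejection threshold applied when `results` is numeric.
#' @return List of class `deg_result`: `n_segments`, `n_significant`,
#'   `n_excluded`, `deg_percent`.
#' @examples
#' degree_of_nonlinearity(c(2.5, -2.0, 1.0, 0.5))  # DEG = 50%
#' @export
degree_of_nonlinearity <- function(results, threshold = 1.96) {
  if (length(results) == 0) stop("empty result list")
  if (is.numeric(results)) {
    z <- results
    rejected <- abs(z) > threshold
  } else {
    stopifnot(all(vapply(results, inherits, logical(1), "nl_test_result")))
    z <- vapply(results, `[[`, numeric(1), "z")
    rejected <- vapply(results, function(r)
      if (isTRUE(r$valid)) r$rejected else NA, logical(1))
  }
  valid <- !is.na(rejected)
  n <- sum(valid)
  if (n == 0) stop("all segments had undefined z statistics")
  nsig <- sum(rejected[valid])
  structure(list(n_segments = n, n_significant = nsig,
                 n_excluded = sum(!valid),
                 deg_percent = 100 * nsig / n),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("<deg_result> DEG = %.1f%% (%d of %d segments; %d excluded)\n",
              x$deg_percent, x$n_significant, x$n_segments, x$n_excluded))
  invisible(x)
}
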