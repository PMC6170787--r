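# Butterworth band-pass design via the classical route: analog low-pass
# prototype -> analog band-pass transform -> bilinear transform. The
# polynomial form is validated against scipy.signal.butter coefficient-for-
# coefficient at dev time; filtering itself runs as a cascade of second-order
# sections, which stays numerically stable even for very narrow bands
# (e.g. delta, 1-1.5 Hz) where the expanded polynomial is singular.

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0) - c(0, p) * ri
  p
}

butter_bandpass_zpk <- function(low_hz, high_hz, rate, order = 4) {
  if (low_hz <= 0 || high_hz >= rate / 2 || low_hz >= high_hz)
    stop("band edges must satisfy 0 < low < high < rate/2")
  n <- as.integer(order)
  k <- seq_len(n)
  # analog prototype poles on the unit left-half circle
  p <- exp(1i * pi * (2 * k - 1 + n) / (2 * n))
  fs2 <- 2 * rate
  w1 <- fs2 * tan(pi * low_hz / rate)   # prewarped edges
  w2 <- fs2 * tan(pi * high_hz / rate)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each prototype pole maps to a conjugate pair
  ps <- p * bw / 2
  disc <- sqrt(ps^2 - w0^2)
  poles_s <- c(ps + disc, ps - disc)
  zeros_s <- rep(0 + 0i, n)
  gain_s <- bw^n
  poles_z <- (fs2 + poles_s) / (fs2 - poles_s)
  zeros_z <- (fs2 + zeros_s) / (fs2 - zeros_s)
  gain_z <- gain_s * Re(prod(fs2 - zeros_s) / prod(fs2 - poles_s))
  zeros_z <- c(zeros_z, rep(-1 + 0i, length(poles_z) - length(zeros_z)))
  list(zeros = zeros_z, poles = poles_z, gain = gain_z)
}

#' Design a digital Butterworth band-pass filter
#'
#' @param low_hz,high_hz Band edges in Hz (must lie inside (0, rate/2)).
#' @param rate Sampling rate in Hz.
#' @param order Prototype order per pass (default 4). Forward-backward
#'   application doubles the effective order.
#' @return List with numerator `b` and denominator `a` coefficient vectors
#'   (length `2*order + 1`). For narrow bands prefer the second-order-section
#'   path used internally by [bandpass_zero_phase()].
#' @export
butter_bandpass <- function(low_hz, high_hz, rate, order = 4) {
  zpk <- butter_bandpass_zpk(low_hz, high_hz, rate, order)
  list(b = Re(poly_from_roots(zpk$zeros)) * zpk$gain,
       a = Re(poly_from_roots(zpk$poles)))
}

# cascade of biquads: each row (b0, b1, b2, a1, a2); the overall gain is
# folded into the first section. Each section gets one z=+1 and one z=-1 zero.
butter_bandpass_sos <- function(low_hz, high_hz, rate, order = 4) {
  zpk <- butter_bandpass_zpk(low_hz, high_hz, rate, order)
  poles <- zpk$poles
  pos <- poles[Im(poles) > 1e-14]
  real_p <- poles[abs(Im(poles)) <= 1e-14]
  sec_poles <- c(as.list(pos),
                 if (length(real_p)) split(Re(real_p),
                                           ceiling(seq_along(real_p) / 2)))
  ns <- length(sec_poles)
  sos <- matrix(0, ns, 5)
  for (i in seq_len(ns)) {
    p <- sec_poles[[i]]
    if (is.complex(p)) { a1 <- -2 * Re(p); a2 <- Mod(p)^2 }
    else { a1 <- -sum(p); a2 <- prod(p) }
    sos[i, ] <- c(1, 0, -1, a1, a2)  # zeros at z = +1 and z = -1
  }
  sos[1, 1:3] <- sos[1, 1:3] * zpk$gain
  sos
}

# steady-state initial condition of one biquad for a unit-step input
biquad_zi <- function(b0, b1, b2, a1, a2) {
  # state update (direct form II transposed): z' = A z + B u, y = b0 u + z0
  A <- matrix(c(-a1, 1, -a2, 0), 2, 2, byrow = TRUE)
  B <- c(b1 - a1 * b0, b2 - a2 * b0)
  solve(diag(2) - A, B)
}

sos_filter_pass <- function(sos, x, scale_first) {
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- c(1, sos[i, 4:5])
    # only the first section sees a non-zero steady state: every section has
    # a zero at DC, so downstream steady-state inputs are 0
    zi <- if (i == 1) biquad_zi(b[1], b[2], b[3], a[2], a[3]) * scale_first
          else c(0, 0)
    x <- iir_filter_cpp(b, a, x, zi)
  }
  x
}

# zero-phase forward-backward filtering with odd-reflection padding
filtfilt_sos <- function(sos, x) {
  padlen <- 3 * (2 * nrow(sos) + 1)
  n <- length(x)
  if (n <= padlen)
    stop("input too short for zero-phase filtering (need > ", padlen, " samples)")
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(pre, x, post)
  y <- sos_filter_pass(sos, ext, ext[1])
  y <- rev(sos_filter_pass(sos, rev(y), y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

# kept for the transfer-function tests: filtfilt on the (b, a) polynomial form
filter_zi <- function(b, a) {
  nf <- max(length(b), length(a))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  b <- b / a[1]; a <- a / a[1]
  n <- nf - 1
  A <- rbind(-a[2:nf], cbind(diag(1, n - 1), 0))
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(n) - t(A), B)
}

filtfilt_bw <- function(b, a, x) {
  nf <- max(length(b), length(a))
  padlen <- 3 * nf
  n <- length(x)
  if (n <= padlen)
    stop("input too short for zero-phase filtering (need > ", padlen, " samples)")
  zi <- filter_zi(b, a)
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(pre, x, post)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}
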