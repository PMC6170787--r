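# Independent brute-force oracles for the nonlinear measures. These follow
# the defining formulas step by step with plain loops, deliberately sharing
# no code with the package implementations.

oracle_higuchi <- function(x, k_max = 8) {
  N <- length(x)
  Lk <- numeric(k_max)
  for (k in 1:k_max) {
    Lm <- numeric(k)
    for (m in 1:k) {
      nmax <- floor((N - m) / k)
      s <- 0
      for (i in 1:nmax) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Lm[m] <- s * (N - 1) / (nmax * k^2)
    }
    Lk[k] <- mean(Lm)
  }
  lk <- log(Lk); lkk <- log(1:k_max)
  # closed-form OLS slope
  -(sum((lkk - mean(lkk)) * (lk - mean(lk))) / sum((lkk - mean(lkk))^2))
}

oracle_katz <- function(x) {
  N <- length(x)
  L <- 0
  for (i in 1:(N - 1)) L <- L + sqrt(1 + (x[i + 1] - x[i])^2)
  d <- 0
  for (i in 1:N) d <- max(d, sqrt((i - 1)^2 + (x[i] - x[1])^2))
  n <- N - 1
  log10(n) / (log10(n) + log10(d / L))
}

# Lempel-Ziv 1976 exhaustive-history phrase count by direct substring search
# (reproducibility = the phrase minus its last symbol occurs as a substring
# starting somewhere before the phrase's start, overlap allowed).
oracle_lzc <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  c <- 0L
  start <- 1L
  while (start <= n) {
    k <- 1L
    # grow the phrase while its prefix of length k is reproducible
    while (start + k - 1L <= n) {
      phrase_head <- substr(s, start, start + k - 1L)
      # search for phrase_head starting at any position < start
      found <- FALSE
      if (start > 1L) {
        for (p in 1:(start - 1L)) {
          if (p + k - 1L <= n && substr(s, p, p + k - 1L) == phrase_head) {
            found <- TRUE
            break
          }
        }
      }
      if (!found) break
      k <- k + 1L
    }
    c <- c + 1L
    start <- start + k
  }
  c
}

oracle_sampen <- function(x, m = 2, r_factor = 0.2) {
  N <- length(x)
  r <- r_factor * sd(x)
  A <- 0L; B <- 0L
  for (i in 1:(N - m - 1)) {
    for (j in (i + 1):(N - m)) {
      dm <- 0
      for (k in 0:(m - 1)) dm <- max(dm, abs(x[i + k] - x[j + k]))
      if (dm <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)  # undefined: no log of zero
  -log(A / B)
}

# direct bispectral estimate across independent realizations: the biphase
# phi(f1) + phi(f2) - phi(f1+f2) is locked at 0 under quadratic phase
# coupling, so the mean resultant of exp(i * biphase) over realizations
# approaches 1; phase randomization draws the three rotation angles
# independently, making the biphase uniform and the resultant ~ 1/sqrt(n)
oracle_biphase_resultant <- function(series_list, rate, f1, f2) {
  acc <- 0 + 0i
  for (x in series_list) {
    n <- length(x)
    X <- fft(x)
    i1 <- round(f1 * n / rate) + 1L
    i2 <- round(f2 * n / rate) + 1L
    i3 <- round((f1 + f2) * n / rate) + 1L
    biphase <- Arg(X[i1]) + Arg(X[i2]) - Arg(X[i3])
    acc <- acc + exp(1i * biphase)
  }
  Mod(acc) / length(series_list)
}

# analytic-signal amplitude envelope via the frequency-domain Hilbert method
signal_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}
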