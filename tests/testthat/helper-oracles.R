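# Independent oracles, kept deliberately naive and separate from the package
# code paths they check.

# Natural cubic spline by direct tridiagonal solve of the second-derivative
# system (M_1 = M_n = 0), evaluated piecewise.
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, b)
  vapply(xout, function(xo) {
    j <- max(1, min(n - 1, findInterval(xo, x)))
    d <- xo - x[j]
    hj <- h[j]
    (M[j] * (x[j + 1] - xo)^3 + M[j + 1] * d^3) / (6 * hj) +
      (y[j] / hj - M[j] * hj / 6) * (x[j + 1] - xo) +
      (y[j + 1] / hj - M[j + 1] * hj / 6) * d
  }, numeric(1))
}

# Brute-force Granger F via explicit normal equations for the restricted and
# unrestricted lagged regressions.
brute_granger_F <- function(target, source, p) {
  T_n <- length(target)
  t_idx <- (p + 1):T_n
  y <- target[t_idx]
  Xr <- cbind(1, sapply(1:p, function(j) target[t_idx - j]))
  Xu <- cbind(Xr, sapply(1:p, function(j) source[t_idx - j]))
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rss_r <- rss(Xr)
  rss_u <- rss(Xu)
  df_denom <- (T_n - p) - 2 * p - 1
  ((rss_r - rss_u) / p) / (rss_u / df_denom)
}

# Stationary covariance of a VAR(1) z_t = A z_{t-1} + e_t, Var(e) = Q, by the
# vectorized discrete Lyapunov equation; returns the lag-1 cross-correlation
# of source (leading) with target.
var1_lag1_crosscorr <- function(A, Q, source, target) {
  k <- nrow(A)
  S <- matrix(solve(diag(k * k) - kronecker(A, A), as.vector(Q)), k, k)
  C1 <- A %*% S  # Cov(z_t, z_{t-1}) = A S
  C1[target, source] / sqrt(S[target, target] * S[source, source])
}

# Bivariate VAR(1) sample path with unidirectional coupling a: x -> y.
gen_var1_pair <- function(seed, n, a, burn = 200) {
  set.seed(seed)
  z <- matrix(0, n + burn, 2)
  e <- matrix(rnorm((n + burn) * 2), ncol = 2)
  z[1, ] <- e[1, ]
  for (t in 2:(n + burn)) z[t, ] <- c(0, a * z[t - 1, 1]) + e[t, ]
  z[(burn + 1):(burn + n), ]
}

# Least-squares fit of amplitude and phase of a sinusoid at known frequency.
fit_sinusoid <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  X <- cbind(1, sin(2 * pi * f * t), cos(2 * pi * f * t))
  beta <- qr.solve(X, x)
  list(amplitude = sqrt(beta[2]^2 + beta[3]^2),
       phase = atan2(beta[3], beta[2]))
}

# Analog Butterworth amplitude response |H(f)| = 1/sqrt(1 + (f/fc)^(2n)).
butter_gain <- function(f, fc, n) 1 / sqrt(1 + (f / fc)^(2 * n))
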