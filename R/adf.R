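# Response-surface approximation to the Dickey-Fuller tau distribution
# (MacKinnon 1994), constant-only regression, one variable. p-values are
# Phi(polynomial(tau)) with a quadratic below tau* and a quartic above.
mackinnon_p <- function(stat) {
  tau_star <- -1.61
  tau_min <- -18.83
  tau_max <- 2.74
  small <- c(2.1659, 1.4412, 0.038269)
  large <- c(1.7339, 0.93202, -0.12745, -0.010368)
  if (stat > tau_max) return(1)
  if (stat < tau_min) return(0)
  co <- if (stat <= tau_star) small else large
  stats::pnorm(sum(co * stat^(seq_along(co) - 1)))
}

# least squares with coefficient standard errors
ols_fit <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("singular regressor matrix")
  coef <- qr.coef(qr_x, y)
  resid <- y - drop(X %*% coef)
  rss <- sum(resid^2)
  df <- length(y) - ncol(X)
  s2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(xtx_inv) * s2)
  list(coef = coef, se = se, resid = resid, rss = rss, df = df)
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Screens a series for stationarity before Granger testing. Fits
#' `diff(y)[t] ~ 1 + y[t-1] + diff(y)[t-1..k]` by least squares, with the
#' augmentation order `k` chosen by AIC (on a common sample aligned at the
#' maximum lag, then refit on the full available sample). The statistic is
#' the t-ratio of the `y[t-1]` coefficient and the approximate p-value comes
#' from the MacKinnon (1994) response-surface constants for the constant-only
#' case. Small (negative) statistics reject the unit root.
#'
#' @param x Numeric series, length > 10 + lags.
#' @param max_lag Maximum augmentation order; default is the Schwert rule
#'   `floor(12 * (T/100)^0.25)`.
#' @param alpha Significance level for the `stationary` flag.
#' @return An object of class `adf_result`: `statistic`, `p_value`, `lags`,
#'   `stationary`, `alpha`.
#' @export
adf_test <- function(x, max_lag = NULL, alpha = 0.05) {
  T_n <- length(x)
  if (stats::sd(x) == 0) stop("constant series: degenerate ADF regression")
  if (is.null(max_lag)) max_lag <- floor(12 * (T_n / 100)^0.25)
  max_lag <- min(max_lag, T_n %/% 2 - 3L)
  max_lag <- max(max_lag, 0L)
  if (T_n <= 10 + max_lag) stop("series too short for the ADF regression")
  dy <- diff(x)
  build <- function(k, start) {
    # rows are t = start..length(dy), modelling dy[t]
    t_idx <- (start):length(dy)
    X <- cbind(1, x[t_idx])  # intercept, y_{t-1}
    if (k > 0) for (j in seq_len(k)) X <- cbind(X, dy[t_idx - j])
    list(X = X, y = dy[t_idx])
  }
  # AIC selection on a common sample aligned at max_lag
  start_common <- max_lag + 1L
  aic <- vapply(0:max_lag, function(k) {
    d <- build(k, start_common)
    f <- ols_fit(d$X, d$y)
    n <- length(d$y)
    n * log(f$rss / n) + 2 * ncol(d$X)
  }, numeric(1))
  k_best <- (0:max_lag)[which.min(aic)]
  d <- build(k_best, k_best + 1L)
  f <- ols_fit(d$X, d$y)
  stat <- f$coef[2] / f$se[2]
  p <- mackinnon_p(stat)
  structure(list(statistic = unname(stat), p_value = p, lags = k_best,
                 stationary = p < alpha, alpha = alpha),
            class = "adf_result")
}

#' @export
print.adf_result <- function(x, ...) {
  cat(sprintf("ADF test: tau = %.3f, lags = %d, p ~ %.4f -> %s at alpha = %g\n",
              x$statistic, x$lags, x$p_value,
              if (x$stationary) "stationary" else "unit root not rejected",
              x$alpha))
  invisible(x)
}
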