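#' Select the VAR lag order by AIC
#'
#' Fits the bivariate vector autoregression of `(x, y)` by least squares for
#' every lag order `p = 1..max_lag` and returns the order minimizing the
#' small-sample-corrected Akaike criterion
#' `AICc(p) = log det(Sigma_ML) + 2 k / (T_eff - k_eq - 3)`, where `Sigma_ML`
#' is the maximum-likelihood residual covariance, `k = 2 (1 + 2p)` the number
#' of estimated coefficients, `k_eq = 1 + 2p` the per-equation count and
#' `T_eff = T - p` the per-lag effective sample (each candidate order is
#' aligned on its own sample). Away from the feasibility boundary the
#' corrected penalty is indistinguishable from the plain `2 k / T_eff`; near
#' it, where per-equation parameters approach the sample size, the plain
#' criterion degenerates (the residual determinant collapses mechanically and
#' the maximal order always wins), and the correction restores consistent
#' selection. Ties break toward the smallest order. Orders that would leave
#' too few residual degrees of freedom are infeasible, so `max_lag` is
#' reduced below `(T - 1)/3` with a warning when necessary.
#'
#' @param x,y Equal-length numeric series.
#' @param max_lag Search ceiling (default 120).
#' @return The selected lag order (integer) with the AIC profile in the
#'   `aic` attribute.
#' @export
select_lag_aic <- function(x, y, max_lag = 120) {
  T_n <- length(x)
  if (length(y) != T_n) stop("series must have equal length")
  # need T_eff - k_eq - 3 > 0: (T - p) - (1 + 2p) - 3 > 0, i.e. p < (T - 4)/3
  feasible <- min(floor((T_n - 1) / 3) - 1L, floor((T_n - 5) / 3))
  if (max_lag > feasible) {
    warning(sprintf("max_lag %d reduced to %d for series of length %d",
                    max_lag, feasible, T_n))
    max_lag <- feasible
  }
  if (max_lag < 1L) stop("series too short for any VAR lag")
  aic <- numeric(max_lag)
  for (p in seq_len(max_lag)) {
    t_idx <- (p + 1L):T_n
    Z <- matrix(1, length(t_idx), 1 + 2 * p)
    for (j in seq_len(p)) {
      Z[, 1 + j] <- x[t_idx - j]
      Z[, 1 + p + j] <- y[t_idx - j]
    }
    Y <- cbind(x[t_idx], y[t_idx])
    qr_z <- qr(Z)
    if (qr_z$rank < ncol(Z)) stop("singular regressor matrix at lag ", p)
    E <- Y - Z %*% qr.coef(qr_z, Y)
    T_eff <- length(t_idx)
    Sigma <- crossprod(E) / T_eff
    det_s <- det(Sigma)
    if (det_s <= 0) stop("degenerate residual covariance at lag ", p)
    k <- 2 * (1 + 2 * p)
    k_eq <- 1 + 2 * p
    aic[p] <- log(det_s) + 2 * k / (T_eff - k_eq - 3)
  }
  p_best <- which.min(aic)  # ties resolve to the smallest order
  structure(as.integer(p_best), aic = aic)
}

#' Granger causality F-test
#'
#' Tests whether `source` Granger-causes `target` at lag order `p`: the
#' restricted model regresses the target on an intercept and its own `p`
#' lags; the unrestricted model adds the source's `p` lags. Both are fit by
#' least squares on the common sample of `T - p` observations and compared
#' with `F = ((RSS_r - RSS_u)/p) / (RSS_u / df_denom)` where
#' `df_denom = (T - p) - 2p - 1`. For the 240-sample epoch-averaged series at
#' lag 1 this gives the familiar denominator df of 236.
#'
#' @param target,source Equal-length gap-free series; `length > 3p + 2`.
#' @param lag Lag order `p`.
#' @param labels Optional `c(source_label, target_label)` for printing.
#' @return An object of class `granger_result`: `direction`, `lag`, `F`,
#'   `df_num`, `df_denom`, `p_value`, `rss_restricted`, `rss_unrestricted`.
#' @export
granger_f <- function(target, source, lag, labels = c("source", "target")) {
  T_n <- length(target)
  if (length(source) != T_n) stop("target and source must have equal length")
  if (anyNA(target) || anyNA(source)) stop("series must be gap-free")
  p <- as.integer(lag)
  if (p < 1L) stop("lag must be >= 1")
  if (T_n <= 3 * p + 2) stop("series too short: need length > 3p + 2")
  t_idx <- (p + 1L):T_n
  y <- target[t_idx]
  Xr <- matrix(1, length(t_idx), 1 + p)
  for (j in seq_len(p)) Xr[, 1 + j] <- target[t_idx - j]
  Xu <- cbind(Xr, vapply(seq_len(p), function(j) source[t_idx - j],
                         numeric(length(t_idx))))
  fr <- ols_fit(Xr, y)
  fu <- ols_fit(Xu, y)
  if (fu$rss <= .Machine$double.eps * sum(y^2)) {
    stop("unrestricted model fits perfectly: degenerate F statistic")
  }
  df_denom <- (T_n - p) - 2 * p - 1
  F_stat <- ((fr$rss - fu$rss) / p) / (fu$rss / df_denom)
  structure(list(direction = sprintf("%s -> %s", labels[1], labels[2]),
                 source = labels[1], target = labels[2],
                 lag = p, F = F_stat, df_num = p, df_denom = df_denom,
                 p_value = stats::pf(F_stat, p, df_denom, lower.tail = FALSE),
                 rss_restricted = fr$rss, rss_unrestricted = fu$rss),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("Granger %s: F(%d, %d) = %.3f, p = %.4g (lag %d)\n",
              x$direction, x$df_num, x$df_denom, x$F, x$p_value, x$lag))
  invisible(x)
}

#' Cohen's d between two series
#'
#' Standardized mean difference `|My - Mx| / sqrt((sx^2 + sy^2)/2)` with
#' sample (n-1) standard deviations, reported as a magnitude: one effect size
#' per pair, identical in both test directions.
#'
#' @param x,y Numeric series, not both constant.
#' @return An object of class `effect_size`: `d`, `mean_x`, `mean_y`, `sd_x`,
#'   `sd_y`.
#' @export
cohens_d <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 && sy == 0) stop("both series are constant: Cohen's d undefined")
  structure(list(d = abs(mean(y) - mean(x)) / sqrt((sx^2 + sy^2) / 2),
                 mean_x = mean(x), mean_y = mean(y), sd_x = sx, sd_y = sy),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (Mx = %.3f, My = %.3f, sx = %.3f, sy = %.3f)\n",
              x$d, x$mean_x, x$mean_y, x$sd_x, x$sd_y))
  invisible(x)
}

#' Bilateral Granger causality fit
#'
#' The core pair test: both directions of Granger causality between two limb
#' series at a common lag, with the shared paired Cohen's d attached to both.
#' This is the "no reverse effect" design — every pair is always tested in
#' both directions.
#'
#' @param a,b Equal-length series.
#' @param lag Lag order; if `NULL`, selected by [select_lag_aic()].
#' @param labels `c(label_a, label_b)`.
#' @param max_lag Search ceiling passed to [select_lag_aic()] when `lag` is
#'   `NULL`.
#' @return An object of class `granger_pair`: `ab` (a leads b), `ba` (b leads
#'   a), `effect` (shared `effect_size`), `lag`, `labels`.
#' @export
granger_bilateral <- function(a, b, lag = NULL, labels = c("a", "b"),
                              max_lag = 120) {
  if (is.null(lag)) lag <- select_lag_aic(a, b, max_lag = max_lag)
  ab <- granger_f(target = b, source = a, lag = lag, labels = labels)
  ba <- granger_f(target = a, source = b, lag = lag,
                  labels = rev(labels))
  structure(list(ab = ab, ba = ba, effect = cohens_d(a, b),
                 lag = as.integer(lag), labels = labels),
            class = "granger_pair")
}

#' @export
print.granger_pair <- function(x, ...) {
  cat(sprintf("Bilateral Granger causality (%s vs %s), lag %d\n",
              x$labels[1], x$labels[2], x$lag))
  print(x$ab)
  print(x$ba)
  print(x$effect)
  invisible(x)
}

#' @export
summary.granger_pair <- function(object, alpha = 0.05, ...) {
  res <- data.frame(
    direction = c(object$ab$direction, object$ba$direction),
    lag = object$lag,
    F = c(object$ab$F, object$ba$F),
    df_num = c(object$ab$df_num, object$ba$df_num),
    df_denom = c(object$ab$df_denom, object$ba$df_denom),
    p = c(object$ab$p_value, object$ba$p_value),
    d = object$effect$d,
    stringsAsFactors = FALSE)
  res$significant <- res$p < alpha
  res
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", ""))
}

#' Analyze all limb pairs per reach type
#'
#' The full statistical battery: for every available reach type (`all`,
#' `grasp`, `touch`, `unsuccessful`) and both limb pairs (acting arm vs
#' non-acting arm; acting arm vs legs mean), screens both series for
#' stationarity with [adf_test()] (a failed screen flags the rows and warns
#' but never halts), selects a joint lag by AIC, runs the bilateral Granger
#' test and attaches Cohen's d. p-values are reported raw; significance stars
#' are `*` (p < 0.05) and `***` (p < 0.001). An optional Holm correction can
#' be switched on in the configuration.
#'
#' @param role_series_by_type Named list (per type) of named lists of
#'   `role_series` objects (`acting_arm`, `non_acting_arm`, `legs_mean`).
#' @param config A `kinegc_config`; its `stats` section is used.
#' @return A data frame of class `overflow_results` with one row per ordered
#'   direction: `type`, `n_reaches`, `pair`, `direction`, `lag`, `F`,
#'   `df_num`, `df_denom`, `p`, `p_holm` (if enabled), `d`, `stars`,
#'   `stationary_source`, `stationary_target`.
#' @export
analyze_pairs <- function(role_series_by_type, config = default_config()) {
  st <- config$stats
  pairs <- list(arm = c("acting_arm", "non_acting_arm"),
                legs = c("acting_arm", "legs_mean"))
  rows <- list()
  for (type in names(role_series_by_type)) {
    rs <- role_series_by_type[[type]]
    if (is.null(rs)) next
    adf <- lapply(rs, function(r) adf_test(r$series, alpha = st$alpha))
    for (pn in names(pairs)) {
      la <- pairs[[pn]][1]; lb <- pairs[[pn]][2]
      if (is.null(rs[[la]]) || is.null(rs[[lb]])) next  # role unavailable
      a <- rs[[la]]$series; b <- rs[[lb]]$series
      if (!adf[[la]]$stationary || !adf[[lb]]$stationary) {
        warning(sprintf("non-stationary series in pair %s/%s (type %s); %s",
                        la, lb, type, "proceeding with flagged rows"),
                call. = FALSE)
      }
      fit <- suppressWarnings(
        granger_bilateral(a, b, labels = c(la, lb), max_lag = st$max_lag))
      for (res in list(fit$ab, fit$ba)) {
        rows[[length(rows) + 1L]] <- data.frame(
          type = type, n_reaches = rs[[la]]$n_reaches, pair = pn,
          direction = res$direction, lag = res$lag, F = res$F,
          df_num = res$df_num, df_denom = res$df_denom, p = res$p_value,
          d = fit$effect$d,
          stationary_source = adf[[res$source]]$stationary,
          stationary_target = adf[[res$target]]$stationary,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (isTRUE(st$holm)) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out$stars <- p_stars(out$p)
  class(out) <- c("overflow_results", "data.frame")
  out
}

#' @export
print.overflow_results <- function(x, digits = 3, ...) {
  cat("Bilateral Granger causality results\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, digits)
  df$p <- signif(df$p, digits)
  df$d <- round(df$d, digits)
  print.data.frame(df, row.names = FALSE)
  cat("stars: * p < 0.05, *** p < 0.001 (raw p-values)\n")
  invisible(x)
}

#' @export
summary.overflow_results <- function(object, ...) {
  sig <- object[object$stars != "", , drop = FALSE]
  cat(sprintf("%d direction tests over %d type(s); %d significant at 0.05\n",
              nrow(object), length(unique(object$type)), sum(object$p < 0.05)))
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  [%s] %s: F(%d, %d) = %.2f%s, d = %.2f\n",
                  sig$type[i], sig$direction[i], sig$df_num[i],
                  sig$df_denom[i], sig$F[i], sig$stars[i], sig$d[i]))
    }
  }
  invisible(object)
}
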