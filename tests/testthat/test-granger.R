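test_that("the ADF screen has power against stationarity and size under the null", {
  rej_iid <- vapply(1:100, function(s) {
    set.seed(s)
    adf_test(rnorm(240))$stationary
  }, logical(1))
  expect_gte(mean(rej_iid), 0.99)

  rej_rw <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    adf_test(cumsum(rnorm(240)))$stationary
  }, logical(1))
  expect_lte(mean(rej_rw), 0.10)

  set.seed(2)
  ar <- as.numeric(arima.sim(list(ar = 0.5), 240))
  expect_lt(adf_test(ar)$statistic, 0)
  expect_error(adf_test(rep(1, 240)), "constant")
})

test_that("ADF p-values follow the published response-surface approximation", {
  # anchors of the constant-only tau response surface
  surface <- function(stat) {
    co <- if (stat <= -1.61) c(2.1659, 1.4412, 0.038269)
          else c(1.7339, 0.93202, -0.12745, -0.010368)
    pnorm(sum(co * stat^(seq_along(co) - 1)))
  }
  set.seed(14)
  for (s in 1:5) {
    x <- rnorm(240) + 0.3 * cumsum(rnorm(240))
    res <- adf_test(x)
    expect_equal(res$p_value, surface(res$statistic), tolerance = 1e-12)
  }
})

test_that("AIC lag selection finds the true order of coupled processes", {
  # VAR(1): modal and majority selection of p* = 1
  sel1 <- vapply(1:300, function(s) {
    z <- gen_var1_pair(s, 240, 0.8)
    suppressWarnings(select_lag_aic(z[, 1], z[, 2], max_lag = 120))
  }, integer(1))
  expect_gte(mean(sel1 == 1), 0.80)

  # white noise: small orders
  seln <- vapply(1:100, function(s) {
    set.seed(5000 + s)
    suppressWarnings(select_lag_aic(rnorm(240), rnorm(240), max_lag = 120))
  }, integer(1))
  expect_gte(mean(seln <= 3), 0.90)

  # coupling only at lag 3
  sel3 <- vapply(1:100, function(s) {
    set.seed(7000 + s)
    burn <- 200; n <- 1000
    z <- matrix(0, n + burn, 2)
    e <- matrix(rnorm((n + burn) * 2), ncol = 2)
    for (t in 4:(n + burn)) z[t, ] <- c(0, 0.8 * z[t - 3, 1]) + e[t, ]
    z <- z[(burn + 1):(burn + n), ]
    select_lag_aic(z[, 1], z[, 2], max_lag = 20)
  }, integer(1))
  expect_gte(mean(sel3 == 3), 0.80)
})

test_that("infeasible search ceilings are reduced with a warning", {
  set.seed(1)
  x <- rnorm(240); y <- rnorm(240)
  expect_warning(select_lag_aic(x, y, max_lag = 120), "reduced")
  expect_silent(invisible(select_lag_aic(x, y, max_lag = 10)))
})

test_that("the Granger F degrees of freedom follow the stated identity", {
  for (T_n in c(50, 100, 240, 500)) {
    for (p in c(1, 2, 5, 10)) {
      set.seed(T_n + p)
      res <- granger_f(rnorm(T_n), rnorm(T_n), lag = p)
      expect_equal(res$df_denom, (T_n - p) - 2 * p - 1)
      expect_equal(res$df_num, p)
    }
  }
  set.seed(0)
  r <- granger_f(rnorm(240), rnorm(240), lag = 1)
  expect_equal(r$df_denom, 236L)
})

test_that("granger_f agrees with the brute-force two-regression oracle", {
  set.seed(99)
  for (rep in 1:20) {
    T_n <- sample(c(50, 240), 1)
    p <- sample(c(1, 2, 5), 1)
    x <- rnorm(T_n)
    y <- rnorm(T_n) + 0.3 * c(rep(0, p), x[1:(T_n - p)])
    expect_lt(abs(granger_f(y, x, p)$F - brute_granger_F(y, x, p)), 1e-8)
  }
})

test_that("granger_f agrees with an independent library implementation", {
  skip_if_not_installed("lmtest")
  set.seed(123)
  for (p in c(1, 3)) {
    z <- gen_var1_pair(p, 200, 0.5)
    mine <- granger_f(z[, 2], z[, 1], lag = p)
    ref <- lmtest::grangertest(z[, 2] ~ z[, 1], order = p)
    expect_equal(mine$F, ref$F[2], tolerance = 1e-8)
    expect_equal(mine$p_value, ref$`Pr(>F)`[2], tolerance = 1e-8)
  }
})

test_that("the Granger test keeps nominal size and detects true coupling", {
  # size at alpha = 0.05 under independence
  p_null <- vapply(1:300, function(s) {
    set.seed(s)
    granger_f(rnorm(240), rnorm(240), lag = 1)$p_value
  }, numeric(1))
  expect_gt(mean(p_null < 0.05), 0.02)
  expect_lt(mean(p_null < 0.05), 0.09)

  # power under y_t = 0.8 x_{t-1} + e
  res <- lapply(1:100, function(s) {
    z <- gen_var1_pair(s, 240, 0.8)
    c(fwd = granger_f(z[, 2], z[, 1], 1)$p_value,
      rev = granger_f(z[, 1], z[, 2], 1)$p_value)
  })
  fwd <- vapply(res, `[[`, numeric(1), "fwd")
  rev <- vapply(res, `[[`, numeric(1), "rev")
  expect_gte(mean(fwd < 0.001), 0.95)
  expect_lte(mean(rev < 0.05), 0.12)
})

test_that("F statistics are invariant to common shifts and rescalings", {
  z <- gen_var1_pair(8, 240, 0.5)
  base <- granger_f(z[, 2], z[, 1], 2)$F
  expect_lt(abs(granger_f(z[, 2] + 100, z[, 1] + 100, 2)$F - base), 1e-8)
  expect_lt(abs(granger_f(z[, 2] * 3.7, z[, 1] * 3.7, 2)$F - base), 1e-8)
})

test_that("degenerate Granger inputs raise errors", {
  expect_error(granger_f(rnorm(10), rnorm(10), lag = 5), "too short")
  expect_error(granger_f(rnorm(100), rnorm(99), lag = 1), "equal length")
  t <- 1:100
  expect_error(granger_f(as.numeric(t), as.numeric(t + 1), lag = 1),
               "perfectly|singular")
})

test_that("Cohen's d follows its formula, symmetry and invariances", {
  x <- c(-1, 0, 1)           # mean 0, sd 1
  y <- c(0, 1, 2)            # mean 1, sd 1
  expect_equal(cohens_d(x, y)$d, 1)
  expect_equal(cohens_d(x, x)$d, 0)
  set.seed(10)
  a <- rnorm(240, 2, 1.3)
  b <- rnorm(240, 5, 0.7)
  oracle <- abs(mean(b) - mean(a)) / sqrt((sd(a)^2 + sd(b)^2) / 2)
  expect_lt(abs(cohens_d(a, b)$d - oracle), 1e-12)
  expect_equal(cohens_d(b, a)$d, cohens_d(a, b)$d)
  expect_equal(cohens_d(a + 7, b + 7)$d, cohens_d(a, b)$d, tolerance = 1e-12)
  expect_equal(cohens_d(a * 2, b * 2)$d, cohens_d(a, b)$d, tolerance = 1e-12)
  expect_error(cohens_d(rep(1, 5), rep(2, 5)), "constant")
})

test_that("the bilateral fit is the composition of two directional tests", {
  z <- gen_var1_pair(3, 240, 0.6)
  pair <- granger_bilateral(z[, 1], z[, 2], lag = 1, labels = c("x", "y"))
  ab <- granger_f(target = z[, 2], source = z[, 1], lag = 1,
                  labels = c("x", "y"))
  ba <- granger_f(target = z[, 1], source = z[, 2], lag = 1,
                  labels = c("y", "x"))
  expect_identical(pair$ab$F, ab$F)
  expect_identical(pair$ba$F, ba$F)
  expect_identical(pair$ab$df_denom, pair$ba$df_denom)
  swapped <- granger_bilateral(z[, 2], z[, 1], lag = 1, labels = c("y", "x"))
  expect_identical(swapped$ab$F, pair$ba$F)
  expect_identical(swapped$ba$F, pair$ab$F)
  expect_identical(swapped$effect$d, pair$effect$d)
  s <- summary(pair)
  expect_equal(nrow(s), 2)
  expect_true(all(c("direction", "F", "p", "d") %in% names(s)))
})

test_that("analyze_pairs assembles flagged, starred rows for every pair", {
  mk_role <- function(x) structure(list(series = x, n_reaches = 10,
                                        role = "r", fs = 60, onset_row = 121),
                                   class = "role_series")
  set.seed(21)
  z <- gen_var1_pair(21, 240, 0.9)
  rs <- list(all = list(acting_arm = mk_role(z[, 2]),
                        non_acting_arm = mk_role(z[, 1]),
                        legs_mean = mk_role(rnorm(240))))
  res <- analyze_pairs(rs)
  expect_s3_class(res, "overflow_results")
  expect_equal(nrow(res), 4)  # 2 pairs x 2 directions
  expect_setequal(unique(res$pair), c("arm", "legs"))
  expect_true(all(res$df_denom == (240 - res$lag) - 2 * res$lag - 1))
  strong <- res[res$direction == "non_acting_arm -> acting_arm", ]
  expect_lt(strong$p, 0.001)
  expect_equal(strong$stars, "***")
})
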