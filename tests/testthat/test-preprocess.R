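test_that("point outliers beyond the threshold are nulled and counted", {
  x <- c(1, -2, 75712.38, 3, -39990.56, 4)
  r <- remove_point_outliers(x)
  expect_equal(r$count, 2)
  expect_equal(r$positions, c(3L, 5L))
  expect_true(all(is.na(r$series[c(3, 5)])))
  expect_equal(r$series[-c(3, 5)], x[-c(3, 5)])

  clean <- seq(-150, 150, length.out = 100)
  r2 <- remove_point_outliers(clean)
  expect_equal(r2$count, 0)
  expect_identical(r2$series, clean)

  set.seed(1)
  y <- rnorm(5000)
  pos <- sort(sample(5000, 12))
  y[pos] <- sample(c(-1, 1), 12, TRUE) * runif(12, 200, 9e4)
  oracle <- which(abs(y) > 150)  # linear scan
  r3 <- remove_point_outliers(y)
  expect_equal(r3$count, 12)
  expect_equal(r3$positions, oracle)
  expect_equal(r3$positions, pos)
})

test_that("missingness accounting drives the 25% sensor exclusion rule", {
  expect_equal(missing_proportion(c(1, NA, 3, NA)), 0.5)
  expect_error(missing_proportion(numeric(0)), "empty")
  mk_rec <- function(p_missing) {
    n <- 1000
    x <- rnorm(n)
    x[seq_len(round(p_missing * n))] <- NA
    sensor_recording("left_arm", 60, x, rnorm(n), rnorm(n))
  }
  out30 <- preprocess_sensor(mk_rec(0.30))
  expect_true(out30$report$excluded)
  expect_null(out30$series)
  out18 <- preprocess_sensor(mk_rec(0.18))
  expect_false(out18$report$excluded)
  expect_false(is.null(out18$series))
  out0 <- preprocess_sensor(mk_rec(0))
  expect_false(out0$report$excluded)
  expect_equal(out0$report$missing, 0)
})

test_that("spline interpolation recovers interior gaps and fills edges", {
  # cubic through an interior gap: natural boundary error is negligible there
  t <- 0:100
  y <- 2 + 0.5 * t - 0.03 * t^2 + 0.001 * t^3
  gapped <- y
  gapped[48:52] <- NA
  filled <- interpolate_gaps(gapped)
  expect_lt(max(abs(filled[48:52] - y[48:52])), 1e-9)
  expect_false(anyNA(filled))

  lead <- c(NA, NA, NA, 5, 6, 7, 8)
  expect_equal(interpolate_gaps(lead)[1:3], c(5, 5, 5))
  trail <- c(5, 6, 7, 8, NA, NA)
  expect_equal(interpolate_gaps(trail)[5:6], c(8, 8))
  expect_error(interpolate_gaps(c(1, 2, NA, 3)), "at least 4")

  # random smooth signal, random gaps, against the tridiagonal oracle
  set.seed(42)
  for (rep in 1:5) {
    n <- 300
    sm <- cumsum(rnorm(n))
    sm <- as.numeric(stats::filter(sm, rep(1 / 15, 15), sides = 2,
                                   circular = TRUE))
    gaps <- sort(sample(20:(n - 20), 25))
    x <- sm
    x[gaps] <- NA
    ok <- which(!is.na(x))
    oracle <- natural_spline_oracle(ok, x[ok], gaps)
    filled <- interpolate_gaps(x)
    expect_lt(max(abs(filled[gaps] - oracle)), 1e-8)
  }
})

test_that("acceleration magnitude is the per-sample Euclidean norm", {
  expect_equal(acceleration_magnitude(3, 4, 0), 5)
  expect_equal(acceleration_magnitude(0, 0, 0), 0)
  set.seed(3)
  x <- rnorm(200); y <- rnorm(200); z <- rnorm(200)
  expect_lt(max(abs(acceleration_magnitude(x, y, z) -
                      sqrt(x^2 + y^2 + z^2))), 1e-12)
  expect_error(acceleration_magnitude(1:3, 1:2, 1:3), "equal length")
})

test_that("magnitude is invariant under axis rotation", {
  set.seed(8)
  x <- rnorm(500); y <- rnorm(500); z <- rnorm(500)
  m0 <- acceleration_magnitude(x, y, z)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))  # random orthonormal matrix
  rot <- cbind(x, y, z) %*% R
  m1 <- acceleration_magnitude(rot[, 1], rot[, 2], rot[, 3])
  expect_lt(max(abs(m1 - m0)), 1e-9)
})

test_that("the low-pass filter honours its transfer-function contract", {
  fs <- 60
  # unit DC gain after the transient
  const <- rep(3.7, 2000)
  out <- lowpass_filter(const, fs)
  expect_lt(max(abs(out[1000:2000] - 3.7)), 1e-6)

  # amplitude 1/sqrt(2) at the cutoff
  t <- (0:5999) / fs
  x_fc <- sin(2 * pi * 25 * t)
  y_fc <- lowpass_filter(x_fc, fs)
  amp <- fit_sinusoid(y_fc[2000:6000], 25, fs)$amplitude
  expect_lt(abs(amp - 1 / sqrt(2)), 0.01)

  # closed-form gain at fc/10
  x_lo <- sin(2 * pi * 2.5 * t)
  y_lo <- lowpass_filter(x_lo, fs)
  amp_lo <- fit_sinusoid(y_lo[2000:6000], 2.5, fs)$amplitude
  expect_lt(abs(amp_lo - butter_gain(2.5, 25, 4)), 0.01)

  # forward-backward filtering squares the gain at the cutoff
  y_zp <- lowpass_filter(x_fc, fs, zero_phase = TRUE)
  amp_zp <- fit_sinusoid(y_zp[2000:4000], 25, fs)$amplitude
  expect_lt(abs(amp_zp - 0.5), 0.01)

  expect_error(lowpass_filter(rnorm(100), fs = 40, cutoff = 25), "resample")
})

test_that("the filter impulse response is stable and decaying", {
  imp <- c(1, rep(0, 4999))
  for (spec in list(c(4, 25, 60), c(4, 25, 120), c(2, 10, 60))) {
    h <- lowpass_filter(imp, fs = spec[3], order = spec[1], cutoff = spec[2])
    expect_lt(max(abs(h[4000:5000])), 1e-6)
  }
})

test_that("resampling preserves the time support and signal content", {
  x <- rnorm(100)
  expect_identical(resample_series(x, 60, 60), x)
  expect_equal(length(resample_series(rnorm(400), 40, 60)), 600)
  t40 <- (0:399) / 40
  sig <- sin(2 * pi * 2 * t40 + 0.7)
  res <- resample_series(sig, 40, 60)
  fit <- fit_sinusoid(res, 2, 60)  # new grid shares the t = 0 origin
  expect_lt(abs(fit$amplitude - 1), 0.01)
  expect_lt(abs(fit$phase - 0.7), 0.01 * 2 * pi)
})

test_that("gravity subtraction is an unclipped constant shift", {
  expect_equal(subtract_gravity(rep(9.8, 5)), rep(0, 5))
  expect_equal(subtract_gravity(rep(0, 5)), rep(-9.8, 5))
  set.seed(2)
  x <- rnorm(100)
  expect_identical(subtract_gravity(x), x - 9.8)
})

test_that("preprocessing resamples 40 Hz recordings before filtering", {
  set.seed(6)
  n <- 4000  # 100 s at 40 Hz
  u <- embed_three_axes(abs(rnorm(n, 3, 0.5)), 9.8, seed = 1)
  rec <- sensor_recording("right_arm", 40, u[, 1], u[, 2], u[, 3])
  out <- preprocess_sensor(rec)
  expect_match(out$report$notes, "before filtering")
  expect_equal(length(out$series), round(n * 60 / 40))
  expect_equal(out$fs, 60)
})

test_that("artifact stages are no-ops on clean data", {
  set.seed(9)
  x <- rnorm(500)
  r <- remove_point_outliers(x)
  expect_identical(r$series, x)
  expect_identical(interpolate_gaps(x), x)
  expect_equal(missing_proportion(x), 0)
})
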