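# binary train with block marks at the given onsets (seconds)
block_train <- function(onsets, width_s, fs, n) {
  annotation_train(
    annotation_track(data.frame(onset = onsets, offset = onsets + width_s,
                                category = "kick", hand = "none")),
    fs, c(0, n / fs), n)
}

test_that("the kick window pads and clips around the annotated kicks", {
  mk <- function(onsets) annotation_track(data.frame(
    onset = onsets, offset = onsets + 0.5, category = "kick", hand = "none"))
  expect_equal(kick_window(mk(30), duration = 60), c(15, 45))
  expect_equal(kick_window(mk(5), duration = 60)[1], 0)
  expect_equal(kick_window(mk(c(20, 40)), duration = 60), c(5, 55))
  empty <- annotation_track(data.frame(onset = 1, offset = 2,
                                       category = "grasp", hand = "left"))
  expect_error(kick_window(empty, duration = 60), "synchronization impossible")
})

test_that("activity binarization marks exactly the suprathreshold samples", {
  x <- rep(1, 600)
  spikes <- c(100, 250, 400)
  x[spikes] <- 50
  tr <- binarize_activity(x, 60, c(0, 10))
  expect_equal(which(tr$train == 1L), spikes)
  # k -> large: nothing marked
  tr_inf <- binarize_activity(x + rnorm(600, sd = 0.01), 60, c(0, 10), k = 1e6)
  expect_equal(sum(tr_inf$train), 0)
  expect_error(binarize_activity(rep(2, 600), 60, c(0, 10)), "zero-variance")
})

test_that("binarized synthetic activity overlaps every true kick interval", {
  sim <- simulate_recordings(small_sim_config(seed = 31))
  pp <- preprocess_recordings(sim$recordings)
  kicks <- sim$truth$events[sim$truth$events$category == "kick", ]
  for (leg in c("left_leg", "right_leg")) {
    mine <- kicks[kicks$limb == leg, ]
    if (nrow(mine) == 0) next
    tr <- binarize_activity(pp$series[[leg]], 60, c(0, 200))
    for (i in seq_len(nrow(mine))) {
      idx <- (round(mine$onset[i] * 60) + 1):(round(mine$offset[i] * 60))
      expect_gt(sum(tr$train[idx]), 0)
    }
  }
})

test_that("annotation trains render kick intervals on the sample grid", {
  tr <- annotation_track(data.frame(onset = 10, offset = 10.5,
                                    category = "kick", hand = "none"))
  t1 <- annotation_train(tr, 60, c(0, 20), n = 1200)
  expect_equal(sum(t1$train), 30)
  t2 <- annotation_train(tr, 60, c(15, 20), n = 1200)
  expect_equal(sum(t2$train), 0)
  # round trip through the annotation file format leaves the train unchanged
  path <- tempfile()
  write_annotations(tr, path)
  t3 <- annotation_train(read_annotations(path), 60, c(0, 20), n = 1200)
  expect_identical(t1$train, t3$train)
  unlink(path)
})

test_that("diagonal cross-recurrence recovers shifts, identity and antisymmetry", {
  fs <- 60
  n <- 3600
  a <- block_train(c(10, 22, 37, 48), 0.5, fs, n)
  same <- dcrqa_lag(a, a)
  expect_equal(same$lag_samples, 0L)
  expect_equal(same$peak_rate, mean(a$train == 1L))

  b <- a
  b$train <- c(integer(17), a$train[1:(n - 17)])  # b delayed by 17 samples
  est <- dcrqa_lag(a, b)
  expect_equal(est$lag_samples, 17L)
  expect_equal(dcrqa_lag(b, a)$lag_samples, -17L)

  flat <- a
  flat$train <- rep(1L, n)
  expect_warning(res <- dcrqa_lag(flat, flat), "flat recurrence")
  expect_equal(res$lag_samples, 0L)
  zero <- a
  zero$train <- integer(n)
  expect_error(dcrqa_lag(a, zero), "all-zero")
})

test_that("clean shifted trains are recovered exactly over an offset grid", {
  fs <- 60
  n <- 4800
  set.seed(77)
  onsets <- sort(runif(5, 10, 60))
  a <- block_train(onsets, 0.5, fs, n)
  for (off_s in seq(-3, 3, by = 0.5)) {
    d <- round(off_s * fs)
    b <- a
    b$train <- if (d >= 0) c(integer(d), a$train[1:(n - d)]) else
      c(a$train[(1 - d):n], integer(-d))
    expect_equal(dcrqa_lag(a, b)$lag_samples, d)
  }
})

test_that("applying the estimated lag aligns annotations and is a fixed point", {
  sim <- simulate_recordings(small_sim_config(seed = 5))
  pp <- preprocess_recordings(sim$recordings)
  out <- sync_clocks(pp$series, pp$fs, sim$annotations)
  # identity when no lag
  id <- out$sync
  id$lag_samples <- 0L; id$lag_seconds <- 0
  same <- apply_lag(sim$annotations, id)
  expect_equal(same$events$onset, sim$annotations$events$onset)

  # clean trains: render the truth's sensor-clock kicks and the annotation
  # kicks on one grid; estimated lag equals the injected offset exactly
  fs <- pp$fs
  n <- length(pp$series$left_leg)
  truth_track <- annotation_track(
    sim$truth$events[sim$truth$events$category == "kick",
                     c("onset", "offset", "category", "hand")],
    clock = "sensor")
  t_sensor <- annotation_train(truth_track, fs, c(0, n / fs), n)
  t_ann <- annotation_train(sim$annotations, fs, c(0, n / fs), n)
  est <- dcrqa_lag(t_sensor, t_ann)
  expect_equal(est$lag_seconds, sim$truth$clock_offset, tolerance = 1e-9)
  shifted <- apply_lag(sim$annotations, est)
  expect_equal(shifted$clock, "sensor")
  kicks_shifted <- shifted$events[shifted$events$category == "kick", "onset"]
  kicks_truth <- truth_track$events$onset
  expect_equal(kicks_shifted, kicks_truth, tolerance = 1e-9)

  # fixed point: re-estimating after the shift gives lag 0
  t_shift <- annotation_train(shifted, fs, c(0, n / fs), n)
  expect_equal(dcrqa_lag(t_sensor, t_shift)$lag_samples, 0L)
})

test_that("the full sync stage recovers the offset within the burst plateau", {
  sim <- simulate_recordings(small_sim_config(seed = 19))
  pp <- preprocess_recordings(sim$recordings)
  out <- sync_clocks(pp$series, pp$fs, sim$annotations)
  # sensor marks cover the central part of each kick burst only, so the
  # estimate is exact up to the sub-burst plateau (< half a burst duration)
  expect_lt(abs(out$sync$lag_seconds - sim$truth$clock_offset), 1)
  expect_gt(out$residual_rate, 0)
  expect_true(out$leg %in% c("left_leg", "right_leg"))
})
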