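#' Kick synchronization window
#'
#' The interval used for clock alignment: from `pad` seconds before the first
#' annotated leg kick to `pad` seconds after the last one, clipped to the
#' recording.
#'
#' @param annotations An [annotation_track()] containing at least one kick.
#' @param pad Padding around the first/last kick onset, seconds (default 15).
#' @param duration Recording duration used for clipping, seconds.
#' @return Numeric `c(start, end)` interval in seconds.
#' @export
kick_window <- function(annotations, pad = 15, duration = Inf) {
  stopifnot(inherits(annotations, "annotation_track"))
  kicks <- annotations$events[annotations$events$category == "kick", ]
  if (nrow(kicks) == 0L)
    stop("no kick events: synchronization impossible without kick fiducials")
  c(max(0, min(kicks$onset) - pad), min(duration, max(kicks$onset) + pad))
}

event_train <- function(train, fs, window) {
  structure(list(train = as.integer(train), fs = fs, window = window),
            class = "event_train")
}

#' Binarize sensor activity within an interval
#'
#' Marks a sample active (1) when the magnitude exceeds
#' `median + k * MAD`, both computed within the interval; samples outside the
#' interval are 0. This automates the identification of activity peaks
#' corresponding to kicking movements; the robust threshold is insensitive to
#' the burst outliers it is meant to detect.
#'
#' @param x Magnitude series.
#' @param fs Sampling rate, Hz.
#' @param interval `c(start, end)` in seconds on the series' clock.
#' @param k MAD multiplier (default 3).
#' @return An `event_train` (binary per-sample series over the full support).
#' @export
binarize_activity <- function(x, fs, interval, k = 3) {
  n <- length(x)
  i0 <- max(1L, floor(interval[1] * fs) + 1L)
  i1 <- min(n, ceiling(interval[2] * fs))
  if (i1 < i0) stop("interval lies outside the series support")
  seg <- x[i0:i1]
  s <- stats::mad(seg)
  if (s == 0 && stats::sd(seg) == 0)
    stop("zero-variance series: cannot binarize activity")
  thr <- stats::median(seg) + k * s
  train <- integer(n)
  train[i0:i1][seg > thr] <- 1L
  event_train(train, fs, interval)
}

#' Render kick annotations as a binary train
#'
#' Samples inside any kick annotation interval (intersected with `interval`)
#' become 1 on a sample grid of length `n` starting at time 0.
#'
#' @param annotations An [annotation_track()] with at least one kick.
#' @param fs Sampling rate, Hz.
#' @param interval `c(start, end)` restriction in seconds.
#' @param n Length of the output grid in samples.
#' @return An `event_train`.
#' @export
annotation_train <- function(annotations, fs, interval, n) {
  stopifnot(inherits(annotations, "annotation_track"))
  kicks <- annotations$events[annotations$events$category == "kick", ]
  if (nrow(kicks) == 0L) stop("no kick events to render")
  train <- integer(n)
  for (i in seq_len(nrow(kicks))) {
    a <- max(kicks$onset[i], interval[1])
    b <- min(kicks$offset[i], interval[2])
    if (b <= a) next
    i0 <- max(1L, round(a * fs) + 1L)
    i1 <- min(n, round(b * fs))
    if (i1 >= i0) train[i0:i1] <- 1L
  }
  event_train(train, fs, interval)
}

#' Diagonal cross-recurrence lag estimate
#'
#' For every integer lag `d` in `[-L, L]` (`L = round(max_lag_s * fs)`) the
#' diagonal recurrence rate is the number of coincident marks
#' `a(t) = b(t + d) = 1` divided by the overlap length at that lag. The
#' returned lag maximizes the rate; ties are broken toward the smallest `|d|`
#' and then toward the negative lag. A positive lag means `b`'s marks occur
#' `lag` samples later than `a`'s.
#'
#' When `a` is the sensor-activity train and `b` the annotation train, a
#' positive lag is the amount by which annotation timestamps run ahead of the
#' sensor clock, i.e. the sensor stream lags the annotations; the correction
#' ([apply_lag()]) subtracts `lag_seconds` from all annotation times.
#'
#' @param train_a,train_b `event_train` objects at the same sampling rate.
#' @param max_lag_s Half-width of the lag search, seconds (default 5).
#' @return An object of class `sync_result` with `lag_samples`,
#'   `lag_seconds`, `profile` (data frame of lag, rate) and `peak_rate`.
#' @export
dcrqa_lag <- function(train_a, train_b, max_lag_s = 5) {
  stopifnot(inherits(train_a, "event_train"), inherits(train_b, "event_train"))
  if (train_a$fs != train_b$fs)
    stop("event trains must share a sampling rate")
  fs <- train_a$fs
  a <- train_a$train
  b <- train_b$train
  if (sum(a) == 0L || sum(b) == 0L)
    stop("all-zero event train: no marks to align")
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  L <- round(max_lag_s * fs)
  lags <- (-L):L
  rate <- vapply(lags, function(d) {
    if (d >= 0) {
      ov <- n - d
      if (ov <= 0) return(0) else sum(a[seq_len(ov)] & b[(1 + d):n]) / ov
    } else {
      ov <- n + d
      if (ov <= 0) return(0) else sum(a[(1 - d):n] & b[seq_len(ov)]) / ov
    }
  }, numeric(1))
  if (diff(range(rate)) == 0) {
    warning("flat recurrence profile: returning lag 0")
    best <- which(lags == 0L)
  } else {
    peak <- which(rate == max(rate))
    # ties: smallest |d|, then the negative one
    peak <- peak[order(abs(lags[peak]), lags[peak])]
    best <- peak[1]
  }
  structure(list(lag_samples = lags[best], lag_seconds = lags[best] / fs,
                 fs = fs,
                 profile = data.frame(lag = lags, rate = rate),
                 peak_rate = rate[best]),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> lag %+d samples (%+.3f s), peak recurrence rate %.4f\n",
              x$lag_samples, x$lag_seconds, x$peak_rate))
  invisible(x)
}

#' @export
plot.sync_result <- function(x, ...) {
  graphics::plot(x$profile$lag, x$profile$rate, type = "l",
                 xlab = "lag (samples)", ylab = "diagonal recurrence rate", ...)
  graphics::abline(v = x$lag_samples, lty = 2)
  invisible(x)
}

#' Shift annotations onto the sensor clock
#'
#' Subtracts the estimated lag from every annotation timestamp and relabels
#' the clock as `sensor`. Applying the correction and re-estimating the lag
#' yields 0 (fixed point).
#'
#' @param annotations An [annotation_track()].
#' @param sync A `sync_result` from [dcrqa_lag()].
#' @return An aligned [annotation_track()] with attribute `lag_applied`.
#' @export
apply_lag <- function(annotations, sync) {
  stopifnot(inherits(annotations, "annotation_track"),
            inherits(sync, "sync_result"))
  ev <- annotations$events
  ev$onset <- ev$onset - sync$lag_seconds
  ev$offset <- ev$offset - sync$lag_seconds
  out <- annotation_track(ev, clock = "sensor")
  attr(out, "lag_applied") <- sync$lag_seconds
  out
}

#' Estimate and apply the annotation/sensor clock alignment
#'
#' High-level synchronization: restricts attention to the kick window, picks
#' the leg sensor with the highest variance inside it (unless overridden),
#' binarizes its activity, renders the annotated kicks on the same grid, runs
#' the diagonal cross-recurrence lag search, and shifts the annotations onto
#' the sensor clock. The residual recurrence rate at lag 0 after the shift is
#' recorded as an automated alignment check.
#'
#' @param series Named list of preprocessed magnitude series (needs at least
#'   one leg).
#' @param fs Sampling rate of `series`, Hz.
#' @param annotations An [annotation_track()] on the annotation clock.
#' @param config A `kinegc_config`; its `sync` section is used.
#' @return A list with `annotations` (aligned track), `sync` (the
#'   `sync_result`), `leg` (sensor used) and `residual_rate`.
#' @export
sync_clocks <- function(series, fs, annotations, config = default_config()) {
  s <- config$sync
  n <- max(vapply(Filter(Negate(is.null), series), length, integer(1)))
  duration <- n / fs
  win <- kick_window(annotations, pad = s$pad, duration = duration)
  # the annotated window lives on the annotation clock; widen by the search
  # half-width so the true sensor-side kicks cannot fall outside it
  sensor_win <- c(max(0, win[1] - s$max_lag_s), min(duration, win[2] + s$max_lag_s))
  legs <- c("left_leg", "right_leg")
  legs <- legs[!vapply(series[legs], is.null, logical(1))]
  if (length(legs) == 0L) stop("no leg sensor available for synchronization")
  if (s$leg != "auto") {
    if (is.null(series[[s$leg]])) stop("configured sync leg is excluded: ", s$leg)
    leg <- s$leg
  } else {
    vars <- vapply(legs, function(l) {
      i0 <- max(1L, floor(sensor_win[1] * fs) + 1L)
      i1 <- min(length(series[[l]]), ceiling(sensor_win[2] * fs))
      stats::var(series[[l]][i0:i1])
    }, numeric(1))
    leg <- legs[which.max(vars)]
  }
  sensor_train <- binarize_activity(series[[leg]], fs, sensor_win, k = s$mad_k)
  ann_train <- annotation_train(annotations, fs, win, n = length(series[[leg]]))
  sync <- dcrqa_lag(sensor_train, ann_train, max_lag_s = s$max_lag_s)
  aligned <- apply_lag(annotations, sync)
  shifted_train <- annotation_train(aligned, fs, sensor_win,
                                    n = length(series[[leg]]))
  residual_rate <- mean(sensor_train$train & shifted_train$train)
  list(annotations = aligned, sync = sync, leg = leg,
       residual_rate = residual_rate)
}
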