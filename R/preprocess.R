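#' Null one-point outliers
#'
#' Marks every sample whose absolute value exceeds `threshold` as missing.
#' Tracker glitches produce isolated samples four orders of magnitude above
#' plausible infant limb acceleration; the default threshold of 150 m/s^2 is
#' far above real movement yet far below glitch magnitudes.
#'
#' @param x Numeric axis series (m/s^2), `NA` allowed.
#' @param threshold Positive absolute-value threshold, m/s^2.
#' @return A list with `series` (outliers set to `NA`), `count` and
#'   `positions` (1-based indices).
#' @export
remove_point_outliers <- function(x, threshold = 150) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  pos <- which(!is.na(x) & abs(x) > threshold)
  x[pos] <- NA_real_
  list(series = x, count = length(pos), positions = pos)
}

#' Proportion of missing samples
#'
#' @param x Numeric series.
#' @return Fraction of `NA` samples in `[0, 1]`.
#' @export
missing_proportion <- function(x) {
  if (length(x) == 0L) stop("cannot compute missing proportion of an empty series")
  mean(is.na(x))
}

#' Fill gaps by cubic-spline interpolation
#'
#' Interior missing runs are filled with a natural cubic spline through the
#' non-missing samples; leading and trailing missing runs are filled with the
#' nearest valid value (splines do not extrapolate safely).
#'
#' @param x Numeric series with `NA` gaps; at least 4 valid samples required.
#' @return A gap-free numeric series of the same length.
#' @export
interpolate_gaps <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) < 4L) stop("interpolation requires at least 4 non-missing samples")
  if (length(ok) == length(x)) return(x)
  first <- ok[1]; last <- ok[length(ok)]
  if (first > 1L) x[seq_len(first - 1L)] <- x[first]
  if (last < length(x)) x[(last + 1L):length(x)] <- x[last]
  miss <- which(is.na(x))
  if (length(miss)) {
    x[miss] <- stats::spline(ok, x[ok], method = "natural", xout = miss)$y
  }
  x
}

#' Acceleration magnitude
#'
#' Collapses 3-axis acceleration into its per-sample Euclidean norm
#' `sqrt(x^2 + y^2 + z^2)`.
#'
#' @param x,y,z Equal-length, gap-free axis series (m/s^2).
#' @return Nonnegative magnitude series, m/s^2.
#' @export
acceleration_magnitude <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("axis series must have equal length")
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("axis series must be gap-free (interpolate first)")
  sqrt(x^2 + y^2 + z^2)
}

#' Low-pass Butterworth filter
#'
#' Causal single-pass digital Butterworth filter: the bilinear transform of
#' the analog prototype `|H(f)|^2 = 1 / (1 + (f/fc)^(2n))` with the cutoff
#' pre-warped, giving unit DC gain and amplitude `1/sqrt(2)` at the cutoff.
#' An optional zero-phase (forward-backward) realization squares the gain, so
#' the amplitude at the cutoff becomes 1/2.
#'
#' @param x Gap-free numeric series.
#' @param fs Sampling rate, Hz.
#' @param order Filter order `n` (default 4).
#' @param cutoff Cutoff frequency `fc` in Hz (default 25); must satisfy
#'   `cutoff < fs/2`.
#' @param zero_phase If `TRUE`, filter forward and backward.
#' @return Filtered series.
#' @export
lowpass_filter <- function(x, fs, order = 4, cutoff = 25, zero_phase = FALSE) {
  if (anyNA(x)) stop("series must be gap-free before filtering")
  if (cutoff >= fs / 2) {
    stop(sprintf(paste0("cutoff %g Hz is not below the Nyquist frequency %g Hz; ",
                        "resample to a higher rate first"), cutoff, fs / 2))
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  if (zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Resample a series to a new uniform rate
#'
#' Cubic (natural spline) interpolation onto a uniform grid at `to_fs`,
#' preserving the time support: output length is
#' `round(length(x) * to_fs / from_fs)` with sample `k` at time
#' `(k - 1)/to_fs`.
#'
#' @param x Gap-free numeric series.
#' @param from_fs Original sampling rate, Hz.
#' @param to_fs Target sampling rate, Hz (default 60).
#' @return Resampled series.
#' @export
resample_series <- function(x, from_fs, to_fs = 60) {
  if (from_fs <= 0 || to_fs <= 0) stop("sampling rates must be > 0")
  if (from_fs == to_fs) return(x)
  n <- length(x)
  m <- round(n * to_fs / from_fs)
  t_old <- (seq_len(n) - 1) / from_fs
  t_new <- (seq_len(m) - 1) / to_fs
  t_new <- pmin(t_new, t_old[n])  # do not extrapolate past the last sample
  stats::spline(t_old, x, method = "natural", xout = t_new)$y
}

#' Subtract gravity
#'
#' Removes the constant gravitational contribution from a magnitude series.
#' Values are not clipped: resting samples become slightly negative and stay
#' so.
#'
#' @param x Magnitude series, m/s^2.
#' @param g Gravitational acceleration, m/s^2.
#' @return `x - g`.
#' @export
subtract_gravity <- function(x, g = 9.8) {
  x - g
}

#' Preprocess one sensor recording
#'
#' Applies the fixed stage order: per-axis outlier nulling, missingness
#' accounting and the exclusion rule, cubic-spline gap interpolation,
#' magnitude collapse, low-pass filtering, resampling to the target rate, and
#' gravity subtraction. For recordings whose rate is below twice the filter
#' cutoff the Nyquist limit makes filtering impossible at the native rate, so
#' resampling is moved before the filter and the reordering is logged.
#'
#' @param rec A [sensor_recording()].
#' @param config A `kinegc_config` (see [default_config()]); its
#'   `preprocessing` section is used.
#' @return A list with `series` (processed magnitude at the target rate, or
#'   `NULL` if the sensor is excluded), `fs`, and `report` (one-row data frame
#'   with outlier count, missing proportion, exclusion flag and notes).
#' @export
preprocess_sensor <- function(rec, config = default_config()) {
  stopifnot(inherits(rec, "sensor_recording"))
  p <- config$preprocessing
  notes <- character(0)
  axes <- list(x = rec$acc_x, y = rec$acc_y, z = rec$acc_z)
  n_out <- 0L
  for (a in names(axes)) {
    r <- remove_point_outliers(axes[[a]], p$outlier_threshold)
    axes[[a]] <- r$series
    n_out <- n_out + r$count
  }
  miss <- vapply(axes, missing_proportion, numeric(1))
  excluded <- any(miss > p$exclusion_threshold)
  report <- data.frame(sensor = rec$sensor, fs = rec$fs,
                       outliers = n_out, missing = max(miss),
                       excluded = excluded, notes = "",
                       stringsAsFactors = FALSE)
  if (excluded) {
    report$notes <- sprintf("excluded: missingness %.1f%% > %.0f%%",
                            100 * max(miss), 100 * p$exclusion_threshold)
    return(list(series = NULL, fs = p$target_fs, report = report))
  }
  axes <- lapply(axes, interpolate_gaps)
  mag <- acceleration_magnitude(axes$x, axes$y, axes$z)
  fs <- rec$fs
  if (fs < 2 * p$filter_cutoff) {
    notes <- c(notes, sprintf(
      "resampled %g -> %g Hz before filtering (cutoff %g Hz >= Nyquist %g Hz)",
      fs, p$target_fs, p$filter_cutoff, fs / 2))
    mag <- resample_series(mag, fs, p$target_fs)
    fs <- p$target_fs
    mag <- lowpass_filter(mag, fs, p$filter_order, p$filter_cutoff,
                          p$zero_phase)
  } else {
    mag <- lowpass_filter(mag, fs, p$filter_order, p$filter_cutoff,
                          p$zero_phase)
    if (fs != p$target_fs) {
      notes <- c(notes, sprintf("resampled %g -> %g Hz", fs, p$target_fs))
      mag <- resample_series(mag, fs, p$target_fs)
      fs <- p$target_fs
    }
  }
  mag <- subtract_gravity(mag, p$gravity)
  report$notes <- paste(notes, collapse = "; ")
  list(series = mag, fs = fs, report = report)
}

#' Preprocess a set of sensor recordings
#'
#' Runs [preprocess_sensor()] on each recording and assembles the per-sensor
#' bookkeeping into a `preprocess_report`.
#'
#' @param recordings Named list of [sensor_recording()] objects.
#' @param config A `kinegc_config`.
#' @return A list with `series` (named list of processed magnitude series;
#'   excluded sensors are `NULL`), `fs` (target rate) and `report` (class
#'   `preprocess_report`).
#' @export
preprocess_recordings <- function(recordings, config = default_config()) {
  out <- lapply(recordings, preprocess_sensor, config = config)
  report <- do.call(rbind, lapply(out, `[[`, "report"))
  rownames(report) <- NULL
  class(report) <- c("preprocess_report", "data.frame")
  list(series = lapply(out, `[[`, "series"),
       fs = config$preprocessing$target_fs,
       report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocessing report\n")
  print.data.frame(x, row.names = FALSE)
  excl <- x$sensor[x$excluded]
  if (length(excl)) cat("excluded sensors:", paste(excl, collapse = ", "), "\n")
  invisible(x)
}
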