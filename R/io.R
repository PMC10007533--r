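LIMB_LABELS <- c("left_arm", "right_arm", "left_leg", "right_leg")
REACH_TYPES <- c("grasp", "touch", "unsuccessful")

#' Construct a sensor recording
#'
#' A `sensor_recording` holds one wearable sensor's 3-axis acceleration stream
#' (m/s^2) on the sensor clock, together with its sampling rate and limb
#' label. Missing samples are `NA`.
#'
#' @param sensor Limb label, one of `"left_arm"`, `"right_arm"`, `"left_leg"`,
#'   `"right_leg"`.
#' @param fs Sampling rate in Hz. Rates other than 40 or 60 are accepted with
#'   a warning.
#' @param acc_x,acc_y,acc_z Equal-length numeric vectors of per-axis
#'   acceleration (m/s^2); `NA` marks missing samples.
#' @param t0 Time of the first sample on the sensor clock, seconds.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(sensor, fs, acc_x, acc_y, acc_z, t0 = 0) {
  sensor <- match.arg(sensor, LIMB_LABELS)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive number")
  if (!(fs %in% c(40, 60))) warning("unusual sampling rate: ", fs, " Hz")
  n <- length(acc_x)
  if (n == 0L) stop("recording must contain at least one sample")
  if (length(acc_y) != n || length(acc_z) != n)
    stop("acc_x, acc_y, acc_z must have equal length")
  structure(list(sensor = sensor, fs = fs, t0 = t0,
                 acc_x = as.numeric(acc_x), acc_y = as.numeric(acc_y),
                 acc_z = as.numeric(acc_z)),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  n <- length(x$acc_x)
  miss <- sum(is.na(x$acc_x) | is.na(x$acc_y) | is.na(x$acc_z))
  cat(sprintf("<sensor_recording> %s: %d samples at %g Hz (%.1f s), %d missing\n",
              x$sensor, n, x$fs, n / x$fs, miss))
  invisible(x)
}

#' Write a sensor recording as CSV
#'
#' The interchange dialect: `//`-prefixed header comments carrying
#' `sensor=<label>` and `fs=<Hz>`, then columns
#' `sample_index,acc_x,acc_y,acc_z` with 0-based sample indices and blank
#' cells for missing samples.
#'
#' @param rec A `sensor_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  rows <- paste(seq_along(rec$acc_x) - 1L, fmt(rec$acc_x), fmt(rec$acc_y),
                fmt(rec$acc_z), sep = ",")
  writeLines(c(sprintf("// sensor=%s", rec$sensor),
               sprintf("// fs=%s", formatC(rec$fs, digits = 15, format = "g")),
               "sample_index,acc_x,acc_y,acc_z", rows), path)
  invisible(path)
}

#' Read a sensor CSV
#'
#' Parses the dialect written by [write_sensor_csv()]. Blank cells become
#' missing values; gaps in `sample_index` are filled with inserted missing
#' rows (recorded in the `log` attribute); a non-monotone `sample_index` or a
#' missing required column is a format error.
#'
#' @param path Path to a sensor CSV file.
#' @return A `sensor_recording` with a character `log` attribute.
#' @export
read_sensor_csv <- function(path) {
  if (!file.exists(path)) stop("sensor file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "//")]
  body <- lines[!startsWith(lines, "//")]
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^//\\s*([A-Za-z_]+)\\s*=\\s*(.+)\\s*$", h))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- trimws(kv[3])
  }
  if (is.null(meta$sensor) || is.null(meta$fs))
    stop("sensor CSV header must declare sensor=<label> and fs=<Hz>")
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  for (col in c("sample_index", "acc_x", "acc_y", "acc_z")) {
    if (!col %in% names(df)) stop("sensor CSV missing required column: ", col)
  }
  idx <- df$sample_index
  if (any(diff(idx) <= 0)) stop("sensor CSV sample_index is not strictly increasing")
  log <- character(0)
  n <- idx[length(idx)] - idx[1] + 1L
  ax <- ay <- az <- rep(NA_real_, n)
  pos <- idx - idx[1] + 1L
  ax[pos] <- df$acc_x; ay[pos] <- df$acc_y; az[pos] <- df$acc_z
  n_gap <- n - length(idx)
  if (n_gap > 0) {
    log <- c(log, sprintf("inserted %d missing row(s) for sample_index gaps", n_gap))
  }
  rec <- sensor_recording(meta$sensor, as.numeric(meta$fs), ax, ay, az,
                          t0 = idx[1] / as.numeric(meta$fs))
  attr(rec, "log") <- log
  rec
}

#' Construct an annotation track
#'
#' An `annotation_track` is an ordered list of typed behavioral events on a
#' named clock. Reach events (`grasp`, `touch`, `unsuccessful`, `bimanual`)
#' carry a hand (`left`, `right`, `both`); isolated leg-kick events used for
#' clock synchronization carry hand `none`.
#'
#' @param events A data frame with columns `onset`, `offset` (seconds),
#'   `category` and `hand`.
#' @param clock `"annotation"` (video clock) or `"sensor"`.
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(events, clock = c("annotation", "sensor")) {
  clock <- match.arg(clock)
  stopifnot(is.data.frame(events),
            all(c("onset", "offset", "category", "hand") %in% names(events)))
  events$onset <- as.numeric(events$onset)
  events$offset <- as.numeric(events$offset)
  events$category <- as.character(events$category)
  events$hand <- as.character(events$hand)
  if (nrow(events)) {
    if (any(events$onset >= events$offset)) stop("every event needs onset < offset")
    bad_cat <- setdiff(events$category, c(REACH_TYPES, "bimanual", "kick"))
    if (length(bad_cat)) stop("unknown event category: ", paste(bad_cat, collapse = ", "))
    reach <- events$category %in% c(REACH_TYPES, "bimanual")
    if (any(reach & !(events$hand %in% c("left", "right", "both"))))
      stop("reach events must carry hand left/right/both")
    if (any(!reach & events$hand != "none"))
      stop("kick events must carry hand 'none'")
    events <- events[order(events$onset, events$offset), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(events = events, clock = clock), class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  tab <- table(x$events$category)
  cat(sprintf("<annotation_track> %d events on %s clock: %s\n",
              nrow(x$events), x$clock,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

default_tier_map <- function() {
  c(reach_left = "left", reach_right = "right", reach_both = "both",
    kick = "none")
}

#' Write an annotation track as a tab-delimited export
#'
#' Columns `tier`, `begin_ms`, `end_ms`, `value` in the style of an ELAN
#' tab-delimited export. Reaches go to tier `reach_<hand>` with the reach
#' type in `value`; kicks go to tier `kick`.
#'
#' @param track An `annotation_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  ev <- track$events
  tier <- ifelse(ev$category == "kick", "kick", paste0("reach_", ev$hand))
  value <- ifelse(ev$category == "kick", "kick", ev$category)
  ms <- function(s) formatC(s * 1000, digits = 12, format = "g")
  writeLines(paste(tier, ms(ev$onset), ms(ev$offset), value, sep = "\t"), path)
  invisible(path)
}

#' Read a tab-delimited annotation export
#'
#' Parses rows of `tier`, `begin` (ms), `end` (ms), `value` as exported by
#' ELAN. Tiers are mapped to hands through `tier_map`; the `value` column
#' carries the reach type. Rows with `begin >= end` and rows on unknown tiers
#' are skipped, and every skipped row is recorded with a reason in the `log`
#' attribute. Times are converted from milliseconds to seconds and events
#' sorted by onset.
#'
#' @param path Path to a tab-delimited annotation file.
#' @param tier_map Named character vector mapping tier names to hands
#'   (`"none"` marks the kick tier).
#' @return An `annotation_track` on the annotation clock, with a `log`
#'   attribute.
#' @export
read_annotations <- function(path, tier_map = default_tier_map()) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  log <- character(0)
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) {
      log <- c(log, sprintf("row %d skipped: fewer than 4 tab-separated fields", i))
      next
    }
    tier <- f[1]; begin <- as.numeric(f[2]); end <- as.numeric(f[3]); value <- f[4]
    if (!tier %in% names(tier_map)) {
      log <- c(log, sprintf("row %d skipped: unknown tier '%s'", i, tier))
      next
    }
    if (is.na(begin) || is.na(end) || begin >= end) {
      log <- c(log, sprintf("row %d rejected: begin >= end or unparsable time", i))
      next
    }
    hand <- unname(tier_map[tier])
    category <- if (hand == "none") "kick" else value
    rows[[length(rows) + 1L]] <- data.frame(
      onset = begin / 1000, offset = end / 1000,
      category = category, hand = hand, stringsAsFactors = FALSE)
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset = numeric(0), offset = numeric(0),
               category = character(0), hand = character(0),
               stringsAsFactors = FALSE)
  track <- annotation_track(events, clock = "annotation")
  attr(track, "log") <- log
  track
}
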