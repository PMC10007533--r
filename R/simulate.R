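#' Synthetic-study configuration
#'
#' Describes a synthetic four-limb recording session: a latent lag-1
#' vector-autoregressive (VAR(1)) magnitude process per limb with configurable
#' directional coupling, reach and kick bursts, an annotation/sensor clock
#' offset, one-point outliers, missing-data gaps, gravity and measurement
#' noise. The generator's defaults emulate one ~5 min supine baby-gym session.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Recording duration, seconds.
#' @param coupling 4x4 matrix of lag-1 autoregressive coefficients among the
#'   limb latent magnitudes (row = target, column = source), ordered
#'   `left_arm`, `right_arm`, `left_leg`, `right_leg`. Must be stationary
#'   (spectral radius < 1).
#' @param innovation_sd Innovation standard deviation, m/s^2.
#' @param baseline Constant added to the zero-mean latent process before
#'   truncation at zero, m/s^2 (keeps magnitudes nonnegative).
#' @param reach_counts 3x2 integer matrix of reach counts, rows
#'   `grasp`/`touch`/`unsuccessful`, columns `left`/`right`.
#' @param burst_amplitude Peak amplitude of the smooth burst envelope added at
#'   each reach/kick, m/s^2.
#' @param burst_duration Burst envelope duration, seconds.
#' @param n_kicks Number of isolated leg kicks (synchronization fiducials).
#' @param kick_guard Minimum separation between a kick onset and any other
#'   event onset, seconds.
#' @param clock_offset Annotation clock minus sensor clock, seconds
#'   (annotation timestamps run ahead of the sensor clock when positive).
#' @param outlier_count Number of injected one-point outliers.
#' @param outlier_magnitude Absolute value of injected outliers, m/s^2; must
#'   exceed the 150 m/s^2 detection threshold.
#' @param gap_spec Named list (by limb label) of `c(start, length)` missing
#'   blocks in seconds.
#' @param gravity Gravitational acceleration added to the 3-axis embedding,
#'   m/s^2.
#' @param seed Integer seed; all randomness flows from it via per-stage
#'   sub-streams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 60, duration = 300,
                       coupling = matrix(0, 4, 4),
                       innovation_sd = 0.5, baseline = 2,
                       reach_counts = default_reach_counts(),
                       burst_amplitude = 5, burst_duration = 2,
                       n_kicks = 5, kick_guard = 5,
                       clock_offset = 1.5,
                       outlier_count = 6, outlier_magnitude = 5e4,
                       gap_spec = list(), gravity = 9.8, seed = 1L) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  coupling <- as.matrix(coupling)
  if (!all(dim(coupling) == c(4, 4))) stop("coupling must be a 4x4 matrix")
  rho <- max(Mod(eigen(coupling, only.values = TRUE)$values))
  if (rho >= 1) {
    stop(sprintf("coupling matrix is non-stationary: spectral radius %.4f >= 1", rho))
  }
  dimnames(coupling) <- list(LIMB_LABELS, LIMB_LABELS)
  reach_counts <- as.matrix(reach_counts)
  if (!all(dim(reach_counts) == c(3, 2))) stop("reach_counts must be 3x2 (types x hands)")
  dimnames(reach_counts) <- list(REACH_TYPES, c("left", "right"))
  if (burst_duration <= 0) stop("burst_duration must be > 0")
  if (abs(clock_offset) >= duration / 4) stop("|clock_offset| must be < duration/4")
  if (outlier_count > 0 && outlier_magnitude <= 150)
    stop("outlier_magnitude must exceed the 150 m/s^2 detection threshold")
  if (length(gap_spec) && !all(names(gap_spec) %in% LIMB_LABELS))
    stop("gap_spec names must be limb labels")
  structure(list(fs = fs, duration = duration, coupling = coupling,
                 innovation_sd = innovation_sd, baseline = baseline,
                 reach_counts = reach_counts,
                 burst_amplitude = burst_amplitude,
                 burst_duration = burst_duration,
                 n_kicks = n_kicks, kick_guard = kick_guard,
                 clock_offset = round(clock_offset, 3),
                 outlier_count = outlier_count,
                 outlier_magnitude = outlier_magnitude,
                 gap_spec = gap_spec, gravity = gravity,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_reach_counts <- function() {
  m <- matrix(c(3L, 3L, 2L, 2L, 1L, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(REACH_TYPES, c("left", "right")))
  m
}

# deterministic per-stage sub-seed derived from the master seed
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + 7 * k) %% 2147483647L
}

#' Simulate latent limb magnitude series
#'
#' Draws four equal-length limb magnitude series from the configured
#' stationary VAR(1) law: a zero-mean latent process with the configured
#' coupling and innovation sd, plus a constant baseline, truncated at zero so
#' the result is a valid magnitude. The truncation rate is recorded as the
#' `truncation_rate` attribute.
#'
#' @param config A [sim_config()].
#' @return A `round(fs * duration)` x 4 matrix with limb-labelled columns and
#'   a `truncation_rate` attribute.
#' @export
simulate_latent_magnitudes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- round(config$fs * config$duration)
  A <- config$coupling
  set.seed(sub_seed(config$seed, 1L))
  burn <- 200L
  e <- matrix(stats::rnorm((n + burn) * 4, sd = config$innovation_sd),
              ncol = 4)
  z <- matrix(0, n + burn, 4)
  z[1, ] <- e[1, ]
  for (t in 2:(n + burn)) z[t, ] <- drop(A %*% z[t - 1, ]) + e[t, ]
  z <- z[(burn + 1):(burn + n), , drop = FALSE]
  m <- z + config$baseline
  trunc_rate <- mean(m < 0)
  m[m < 0] <- 0
  colnames(m) <- LIMB_LABELS
  attr(m, "truncation_rate") <- trunc_rate
  m
}

#' Embed a magnitude series in three axes
#'
#' Inverts the magnitude collapse: constructs per-sample axis components
#' `(x, y, z)` whose Euclidean norm equals `magnitude + gravity` at every
#' sample. The sensor orientation (unit direction) is drawn once and then
#' perturbed by a smoothed random walk, so directions vary slowly as a worn
#' sensor's would.
#'
#' @param magnitude Nonnegative magnitude series, m/s^2.
#' @param gravity Gravity contribution added to the norm, m/s^2.
#' @param seed Integer seed for the direction process.
#' @return An n x 3 matrix with columns `acc_x`, `acc_y`, `acc_z`.
#' @export
embed_three_axes <- function(magnitude, gravity = 9.8, seed = 1L) {
  neg <- which(magnitude < 0)
  if (length(neg)) {
    stop("negative magnitude at sample index ", neg[1], " (1-based)")
  }
  n <- length(magnitude)
  set.seed(as.integer(seed) %% 2147483647L)
  base <- stats::rnorm(3)
  base <- base / sqrt(sum(base^2))
  walk <- apply(matrix(stats::rnorm(n * 3, sd = 0.05), ncol = 3), 2, cumsum)
  # low-pass the walk with a moving average so direction varies smoothly
  w <- min(31L, max(1L, n))
  if (w > 1L) {
    kern <- rep(1 / w, w)
    walk <- apply(walk, 2, function(col)
      as.numeric(stats::filter(col, kern, sides = 2, circular = TRUE)))
  }
  u <- sweep(walk, 2, base * 5, "+")
  nrm <- sqrt(rowSums(u^2))
  nrm[nrm < 1e-12] <- 1
  u <- u / nrm
  out <- u * (magnitude + gravity)
  colnames(out) <- c("acc_x", "acc_y", "acc_z")
  out
}

hann_burst <- function(amplitude, duration, fs) {
  L <- max(2L, round(duration * fs))
  amplitude * 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
}

place_onsets <- function(k, lo, hi, existing, min_sep_existing, min_sep_self,
                         max_tries = 20000L) {
  placed <- numeric(0)
  for (i in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- round(stats::runif(1, lo, hi), 3)  # ms grid
      if (length(existing) && min(abs(cand - existing)) < min_sep_existing) next
      if (length(placed) && min(abs(cand - placed)) < min_sep_self) next
      placed <- c(placed, cand)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf(paste0("requested events do not fit: placed %d of %d in ",
                          "[%.1f, %.1f] s at separation >= %.1f s"),
                   length(placed), k, lo, hi, min_sep_self))
    }
  }
  sort(placed)
}

#' Inject reach and kick bursts
#'
#' Adds smooth (Hann-envelope) acceleration bursts to the acting hand's
#' magnitude series at each reach onset and to one leg's series at each kick
#' onset. Kicks are temporally isolated: no other event onset falls within the
#' configured guard interval, which is what makes them usable as
#' synchronization fiducials. All onsets keep at least 2 s of margin from the
#' recording edges so full epochs exist around every event.
#'
#' @param magnitudes n x 4 limb magnitude matrix (from
#'   [simulate_latent_magnitudes()]).
#' @param config A [sim_config()].
#' @return A list with the augmented `magnitudes` and an `events` data frame
#'   (`onset`, `offset`, `category`, `hand`, `limb`) on the sensor clock.
#' @export
inject_events <- function(magnitudes, config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  margin <- 2
  lo <- margin
  hi <- config$duration - margin - config$burst_duration
  if (hi <= lo) stop("recording too short for any event with 2 s edge margins")
  set.seed(sub_seed(config$seed, 2L))
  n_reach <- sum(config$reach_counts)
  kicks <- place_onsets(config$n_kicks, lo, hi, numeric(0),
                        Inf, config$kick_guard)
  reach_sep <- config$burst_duration
  reaches <- place_onsets(n_reach, lo, hi, kicks, config$kick_guard, reach_sep)
  # assign types/hands to the shuffled reach onsets
  labels <- do.call(rbind, lapply(REACH_TYPES, function(ty)
    do.call(rbind, lapply(c("left", "right"), function(h) {
      k <- config$reach_counts[ty, h]
      if (k > 0) data.frame(category = rep(ty, k), hand = rep(h, k),
                            stringsAsFactors = FALSE)
    }))))
  if (is.null(labels)) labels <- data.frame(category = character(0),
                                            hand = character(0))
  labels <- labels[sample.int(nrow(labels)), , drop = FALSE]
  kick_leg <- sample(c("left_leg", "right_leg"), config$n_kicks, replace = TRUE)
  env <- hann_burst(config$burst_amplitude, config$burst_duration, fs)
  add_burst <- function(mag, limb, onset) {
    i0 <- round(onset * fs) + 1L
    idx <- i0:min(nrow(mag), i0 + length(env) - 1L)
    mag[idx, limb] <- mag[idx, limb] + env[seq_along(idx)]
    mag
  }
  events <- list()
  if (n_reach > 0) {
    for (i in seq_len(n_reach)) {
      limb <- paste0(labels$hand[i], "_arm")
      magnitudes <- add_burst(magnitudes, limb, reaches[i])
      events[[length(events) + 1L]] <- data.frame(
        onset = reaches[i], offset = reaches[i] + config$burst_duration,
        category = labels$category[i], hand = labels$hand[i], limb = limb,
        stringsAsFactors = FALSE)
    }
  }
  if (config$n_kicks > 0) {
    for (i in seq_len(config$n_kicks)) {
      magnitudes <- add_burst(magnitudes, kick_leg[i], kicks[i])
      events[[length(events) + 1L]] <- data.frame(
        onset = kicks[i], offset = kicks[i] + config$burst_duration,
        category = "kick", hand = "none", limb = kick_leg[i],
        stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, events)
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  list(magnitudes = magnitudes, events = events)
}

#' Apply artifacts and the clock offset
#'
#' Embeds each limb magnitude in three axes, writes one-point outliers into
#' the raw per-axis data, blanks configured missing-data gaps, and shifts all
#' annotation timestamps by `+clock_offset` so the annotation track lives on
#' the (offset) annotation clock. Everything injected is recorded in the
#' returned ground truth.
#'
#' @param magnitudes n x 4 limb magnitude matrix with bursts.
#' @param events Event data frame on the sensor clock (from
#'   [inject_events()]).
#' @param config A [sim_config()].
#' @return A list with `recordings` (named list of [sensor_recording()]),
#'   `annotations` (an [annotation_track()] on the annotation clock) and
#'   `truth` (class `sim_truth`).
#' @export
apply_artifacts_and_offset <- function(magnitudes, events, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(magnitudes)
  fs <- config$fs
  axes <- lapply(seq_along(LIMB_LABELS), function(i)
    embed_three_axes(magnitudes[, LIMB_LABELS[i]], config$gravity,
                     seed = sub_seed(config$seed, 10L + i)))
  names(axes) <- LIMB_LABELS
  gap_masks <- lapply(LIMB_LABELS, function(l) rep(FALSE, n))
  names(gap_masks) <- LIMB_LABELS
  for (l in names(config$gap_spec)) {
    for (g in config$gap_spec[[l]]) {
      i0 <- round(g[1] * fs) + 1L
      i1 <- min(n, i0 + round(g[2] * fs) - 1L)
      if (i0 > n || i1 < i0) next
      gap_masks[[l]][i0:i1] <- TRUE
    }
  }
  set.seed(sub_seed(config$seed, 3L))
  outliers <- NULL
  if (config$outlier_count > 0) {
    # outliers live in observed (non-gap) samples so the ground truth stays
    # consistent with the written raw data
    gap_flat <- unlist(gap_masks, use.names = FALSE)
    pick <- sample(which(!gap_flat), config$outlier_count)
    outliers <- data.frame(
      sensor = LIMB_LABELS[(pick - 1L) %/% n + 1L],
      sample = (pick - 1L) %% n + 1L,
      axis = sample.int(3L, config$outlier_count, replace = TRUE),
      value = sample(c(-1, 1), config$outlier_count, replace = TRUE) *
        config$outlier_magnitude,
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(outliers))) {
      axes[[outliers$sensor[i]]][outliers$sample[i], outliers$axis[i]] <-
        outliers$value[i]
    }
  } else {
    outliers <- data.frame(sensor = character(0), sample = integer(0),
                           axis = integer(0), value = numeric(0))
  }
  warnings <- character(0)
  for (l in LIMB_LABELS) {
    if (!any(gap_masks[[l]])) next
    axes[[l]][gap_masks[[l]], ] <- NA_real_
    runs <- rle(gap_masks[[l]])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values)) {
      win <- c((starts[j] - 1) / fs, ends[j] / fs)
      hit <- events$onset - 2 < win[2] & events$onset + 2 > win[1]
      if (any(hit)) {
        warnings <- c(warnings, sprintf(
          "gap on %s [%.2f, %.2f] s overlaps event window at onset %.3f s",
          l, win[1], win[2], events$onset[which(hit)[1]]))
      }
    }
  }
  recordings <- lapply(LIMB_LABELS, function(l)
    sensor_recording(l, fs, axes[[l]][, 1], axes[[l]][, 2], axes[[l]][, 3]))
  names(recordings) <- LIMB_LABELS
  ann_events <- events[, c("onset", "offset", "category", "hand")]
  ann_events$onset <- round(ann_events$onset + config$clock_offset, 3)
  ann_events$offset <- round(ann_events$offset + config$clock_offset, 3)
  annotations <- annotation_track(ann_events, clock = "annotation")
  truth <- structure(list(
    coupling = config$coupling,
    clock_offset = config$clock_offset,
    events = events,
    outlier_positions = outliers,
    gap_masks = gap_masks,
    truncation_rate = attr(magnitudes, "truncation_rate"),
    warnings = warnings), class = "sim_truth")
  if (length(warnings)) for (w in warnings) warning(w, call. = FALSE)
  list(recordings = recordings, annotations = annotations, truth = truth)
}

#' Simulate a full synthetic recording session
#'
#' Runs the generator end to end: latent VAR(1) magnitudes, reach/kick burst
#' injection, 3-axis embedding, artifact injection and the annotation clock
#' offset. Deterministic given the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return An object of class `kinegc_simulation`: a list with `recordings`,
#'   `annotations`, `truth` and the `config`.
#' @export
simulate_recordings <- function(config = sim_config()) {
  mags <- simulate_latent_magnitudes(config)
  inj <- inject_events(mags, config)
  attr(inj$magnitudes, "truncation_rate") <- attr(mags, "truncation_rate")
  out <- apply_artifacts_and_offset(inj$magnitudes, inj$events, config)
  out$config <- config
  class(out) <- "kinegc_simulation"
  out
}

#' @export
print.kinegc_simulation <- function(x, ...) {
  ev <- x$truth$events
  cat(sprintf(paste0("<kinegc_simulation> %g s at %g Hz: %d reaches, %d kicks, ",
                     "clock offset %+.3f s, %d outliers\n"),
              x$config$duration, x$config$fs,
              sum(ev$category != "kick"), sum(ev$category == "kick"),
              x$truth$clock_offset, nrow(x$truth$outlier_positions)))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits one sensor CSV per limb, the annotation export, and a plain-text
#' ground-truth sidecar (`truth.txt`: key-value header plus the event table).
#'
#' @param sim A `kinegc_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "kinegc_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in names(sim$recordings)) {
    write_sensor_csv(sim$recordings[[l]], file.path(dir, paste0(l, ".csv")))
  }
  write_annotations(sim$annotations, file.path(dir, "annotations.txt"))
  tr <- sim$truth
  con <- file(file.path(dir, "truth.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("clock_offset=%.3f", tr$clock_offset),
    sprintf("truncation_rate=%.6g", tr$truncation_rate),
    sprintf("coupling=%s", paste(formatC(tr$coupling, format = "g"),
                                 collapse = ",")),
    sprintf("outliers=%s", paste(sprintf("%s:%d:%d", tr$outlier_positions$sensor,
                                         tr$outlier_positions$sample,
                                         tr$outlier_positions$axis),
                                 collapse = ";")),
    "# events (sensor clock): onset offset category hand limb"), con)
  utils::write.table(tr$events, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}
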