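#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> preprocess -> synchronize -> epoch ->
#' analyze on one recording session. Every data-changing decision (outlier
#' nulled, sensor excluded, reach skipped, participant below the reach
#' minimum) is recorded in the run manifest's exclusion ledger with a
#' machine-readable reason code, so inputs always reconcile as analyzed plus
#' excluded.
#'
#' @param config A `kinegc_config` (see [default_config()]).
#' @param simulation A `kinegc_simulation` to analyze; or `NULL` to read
#'   recordings from `input_dir`.
#' @param input_dir Directory holding `<limb>.csv` sensor files and
#'   `annotations.txt` (as written by [write_simulation()]); ignored when
#'   `simulation` is given.
#' @param types Reach types to analyze; a type with no reaches is dropped
#'   with a log entry.
#' @return An object of class `overflow_run`: `results`
#'   (an `overflow_results` table), `tables` (rendered text), `manifest`,
#'   `role_series` (per type), and intermediates (`preprocess`, `sync`).
#' @export
run_full <- function(config = default_config(), simulation = NULL,
                     input_dir = NULL,
                     types = c("all", "grasp", "touch", "unsuccessful")) {
  validate_config(config)
  if (is.null(simulation) && is.null(input_dir))
    stop("provide either a simulation or an input directory")
  log <- character(0)
  exclusions <- data.frame(entity = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "kinegc_simulation"))
    recordings <- simulation$recordings
    annotations <- simulation$annotations
    log <- c(log, "inputs: synthetic simulation")
  } else {
    recordings <- lapply(LIMB_LABELS, function(l) {
      f <- file.path(input_dir, paste0(l, ".csv"))
      if (!file.exists(f)) stop("missing sensor file: ", f)
      read_sensor_csv(f)
    })
    names(recordings) <- LIMB_LABELS
    annotations <- read_annotations(file.path(input_dir, "annotations.txt"))
    log <- c(log, sprintf("inputs: read from %s", input_dir))
  }

  pp <- stage("preprocess", preprocess_recordings(recordings, config))
  for (i in seq_len(nrow(pp$report))) {
    r <- pp$report[i, ]
    log <- c(log, sprintf("preprocess %s: %d outliers nulled, %.1f%% missing%s",
                          r$sensor, r$outliers, 100 * r$missing,
                          if (nzchar(r$notes)) paste0("; ", r$notes) else ""))
    if (r$excluded) {
      exclusions <- rbind(exclusions, data.frame(
        entity = r$sensor,
        reason = sprintf("missingness > %.0f%%",
                         100 * config$preprocessing$exclusion_threshold)))
    }
  }

  sync <- stage("sync", sync_clocks(pp$series, pp$fs, annotations, config))
  log <- c(log, sprintf(
    "sync: leg %s, lag %+d samples (%+.3f s), peak rate %.4f, residual %.4f",
    sync$leg, sync$sync$lag_samples, sync$sync$lag_seconds,
    sync$sync$peak_rate, sync$residual_rate))

  reaches <- stage("epochs", select_unimanual(sync$annotations,
                              min_reaches = config$epoching$min_reaches))
  n_bimanual <- sum(sync$annotations$events$category == "bimanual")
  if (n_bimanual) {
    log <- c(log, sprintf("dropped %d bimanual reach(es)", n_bimanual))
  }
  if (attr(reaches, "excluded")) {
    exclusions <- rbind(exclusions, data.frame(
      entity = "participant",
      reason = sprintf("fewer than %d reaches", config$epoching$min_reaches)))
    log <- c(log, sprintf(
      "participant excluded: %d unimanual reaches < minimum %d",
      nrow(reaches), config$epoching$min_reaches))
    manifest <- list(config = config,
                     seed = if (!is.null(simulation)) simulation$config$seed
                            else NA_integer_,
                     exclusions = exclusions, log = log, sync = NULL)
    return(structure(list(results = NULL, tables = character(0),
                          manifest = manifest, role_series = list(),
                          preprocess = pp, sync = sync),
                     class = "overflow_run"))
  }

  role_series <- list()
  for (type in types) {
    sub <- tryCatch(collapse_by_type(reaches, type), error = function(e) NULL)
    if (is.null(sub)) {
      log <- c(log, sprintf("type %s: no reaches, skipped", type))
      next
    }
    mats <- stage("epochs", role_epoch_matrices(pp$series, sub,
                                pre = config$epoching$pre,
                                post = config$epoching$post, fs = pp$fs))
    for (msg in attr(mats[[1]], "skipped")) log <- c(log, msg)
    role_series[[type]] <- lapply(names(mats), function(r)
      average_epochs(mats[[r]], role = r))
    names(role_series[[type]]) <- names(mats)
    log <- c(log, sprintf("type %s: %d epochs of %d samples per role", type,
                          ncol(mats[[1]]), nrow(mats[[1]])))
  }

  results <- stage("analyze", analyze_pairs(role_series, config))
  tables <- render_tables(results)
  manifest <- list(config = config, seed = if (!is.null(simulation))
    simulation$config$seed else NA_integer_,
    exclusions = exclusions, log = log,
    sync = list(lag_samples = sync$sync$lag_samples,
                lag_seconds = sync$sync$lag_seconds,
                leg = sync$leg, residual_rate = sync$residual_rate))
  structure(list(results = results, tables = tables, manifest = manifest,
                 role_series = role_series,
                 preprocess = pp, sync = sync),
            class = "overflow_run")
}

#' @export
print.overflow_run <- function(x, ...) {
  cat(x$tables, sep = "\n")
  invisible(x)
}

#' Reach descriptives across participants
#'
#' Summarizes annotation tracks: total reaches, per-type and per-hand counts,
#' and the mean and SD of per-participant unimanual reach counts.
#'
#' @param tracks A list of [annotation_track()] objects (one per
#'   participant), or a single track.
#' @return A list with `total`, `per_type`, `per_hand`, `mean_per_participant`
#'   and `sd_per_participant`.
#' @export
reach_descriptives <- function(tracks) {
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)
  per <- vapply(tracks, function(tr) {
    ev <- tr$events
    sum(ev$category %in% REACH_TYPES & ev$hand %in% c("left", "right"))
  }, numeric(1))
  all_ev <- do.call(rbind, lapply(tracks, function(tr) tr$events))
  uni <- all_ev[all_ev$category %in% REACH_TYPES &
                  all_ev$hand %in% c("left", "right"), , drop = FALSE]
  list(total = nrow(uni),
       per_type = table(factor(uni$category, REACH_TYPES)),
       per_hand = table(factor(uni$hand, c("left", "right"))),
       mean_per_participant = mean(per),
       sd_per_participant = stats::sd(per))
}

#' Render results in the two-direction table layout
#'
#' Formats the bilateral Granger results as two text tables (arm pair; legs
#' pair), each split by direction, with columns reaching type, number of
#' reaches, F statistic with stars, and Cohen's d. Stars mark `*` p < 0.05
#' and `***` p < 0.001.
#'
#' @param results An `overflow_results` table from [analyze_pairs()].
#' @return A character vector of table lines.
#' @export
render_tables <- function(results) {
  titles <- c(arm = "Acting arm vs non-acting arm",
              legs = "Acting arm vs legs (mean)")
  lines <- character(0)
  for (pn in c("arm", "legs")) {
    sub <- results[results$pair == pn, , drop = FALSE]
    if (nrow(sub) == 0L) next
    lines <- c(lines, titles[[pn]], strrep("=", nchar(titles[[pn]])))
    for (dir in unique(sub$direction)) {
      d <- sub[sub$direction == dir, , drop = FALSE]
      lines <- c(lines, sprintf("-- %s --", dir),
                 sprintf("%-14s %8s %12s %8s", "Reaching type", "Reaches",
                         "F-statistic", "d"))
      for (i in seq_len(nrow(d))) {
        lines <- c(lines, sprintf("%-14s %8d %12s %8.2f", d$type[i],
                                  d$n_reaches[i],
                                  paste0(formatC(d$F[i], format = "f",
                                                 digits = 2), d$stars[i]),
                                  d$d[i]))
      }
    }
    lines <- c(lines, "Note: * p < 0.05, *** p < 0.001", "")
  }
  lines
}
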