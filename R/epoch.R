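#' Select unimanual reaches
#'
#' Keeps reaches executed with one hand (`left` or `right`) and drops
#' bimanual ones, since overflow in an arm can only be registered when the
#' other arm is acting. Per-type and per-hand counts are recorded in the
#' `counts` attribute; whether the participant meets the minimum reach count
#' is recorded in the `excluded` attribute.
#'
#' @param annotations An [annotation_track()] aligned to the sensor clock.
#' @param min_reaches Minimum number of unimanual reaches required for the
#'   participant to be analyzed (default 4).
#' @return Data frame of unimanual reach events with attributes `counts` and
#'   `excluded`.
#' @export
select_unimanual <- function(annotations, min_reaches = 4) {
  stopifnot(inherits(annotations, "annotation_track"))
  ev <- annotations$events
  reaches <- ev[ev$category %in% REACH_TYPES & ev$hand %in% c("left", "right"), ,
                drop = FALSE]
  if (nrow(reaches) == 0L) stop("no unimanual reaches to analyze")
  rownames(reaches) <- NULL
  attr(reaches, "counts") <- table(factor(reaches$category, REACH_TYPES),
                                   factor(reaches$hand, c("left", "right")))
  attr(reaches, "excluded") <- nrow(reaches) < min_reaches
  reaches
}

#' Assign limb roles for one reach
#'
#' Maps the four preprocessed limb series onto the roles the pair tests use:
#' the acting arm (matching the reach's hand), the non-acting arm (the
#' contralateral arm) and the per-sample mean of the two legs.
#'
#' @param series Named list of preprocessed magnitude series (limb labels).
#' @param hand `"left"` or `"right"`.
#' @return Named list `acting_arm`, `non_acting_arm`, `legs_mean`, or `NULL`
#'   (with a message) when a required sensor is excluded.
#' @export
assign_roles <- function(series, hand) {
  hand <- match.arg(hand, c("left", "right"))
  acting <- paste0(hand, "_arm")
  non_acting <- paste0(setdiff(c("left", "right"), hand), "_arm")
  needed <- c(acting, non_acting, "left_leg", "right_leg")
  missing <- needed[vapply(series[needed], is.null, logical(1))]
  if (length(missing)) {
    message("reach skipped: excluded sensor(s) needed for a role: ",
            paste(missing, collapse = ", "))
    return(NULL)
  }
  list(acting_arm = series[[acting]],
       non_acting_arm = series[[non_acting]],
       legs_mean = (series$left_leg + series$right_leg) / 2)
}

#' Extract event-locked epochs
#'
#' Cuts a fixed window around every onset: samples in
#' `[round(onset * fs) - pre * fs, round(onset * fs) + post * fs)` (half-open,
#' 0-based) become one column. Onsets whose window exceeds the recording are
#' skipped and logged in the `skipped` attribute so event counts stay
#' auditable. At the defaults (2 s pre, 2 s post, 60 Hz) each epoch is 240
#' samples with the onset at row 121 (1-based).
#'
#' @param x Gap-free magnitude series.
#' @param onsets Reach onset times, seconds, on the series' clock.
#' @param pre,post Window extent before/after the onset, seconds.
#' @param fs Sampling rate, Hz.
#' @param meta Optional data frame of per-onset metadata (kept for retained
#'   columns).
#' @return An `epoch_matrix`: samples x reaches matrix with attributes `fs`,
#'   `pre`, `post`, `onset_row` (1-based), `meta` and `skipped`.
#' @export
extract_epochs <- function(x, onsets, pre = 2, post = 2, fs = 60, meta = NULL) {
  n <- length(x)
  rows <- round((pre + post) * fs)
  pre_s <- round(pre * fs)
  cols <- list()
  keep <- logical(length(onsets))
  skipped <- character(0)
  for (i in seq_along(onsets)) {
    c0 <- round(onsets[i] * fs)  # 0-based onset sample
    lo <- c0 - pre_s             # 0-based, inclusive
    hi <- lo + rows - 1L
    if (lo < 0L || hi >= n) {
      skipped <- c(skipped, sprintf(
        "onset %.3f s skipped: window [%d, %d] outside recording of %d samples",
        onsets[i], lo, hi, n))
      next
    }
    keep[i] <- TRUE
    cols[[length(cols) + 1L]] <- x[(lo + 1L):(hi + 1L)]
  }
  if (length(cols) == 0L) stop("no usable onsets: every epoch window exceeds the recording")
  m <- do.call(cbind, cols)
  structure(m, fs = fs, pre = pre, post = post, onset_row = pre_s + 1L,
            meta = if (!is.null(meta)) meta[keep, , drop = FALSE] else NULL,
            skipped = skipped,
            class = c("epoch_matrix", class(m)))
}

#' Average epochs into one role series
#'
#' Per-sample arithmetic mean across reaches (columns), yielding one averaged
#' time series per limb role whose length equals the epoch length.
#'
#' @param m An `epoch_matrix` (or plain matrix) with at least one column.
#' @param role Optional role label.
#' @return A `role_series`: list with `series`, `n_reaches`, `role`, `fs`,
#'   `onset_row`.
#' @export
average_epochs <- function(m, role = NA_character_) {
  if (ncol(m) < 1L) stop("epoch matrix must contain at least one reach")
  structure(list(series = rowMeans(m), n_reaches = ncol(m), role = role,
                 fs = attr(m, "fs"), onset_row = attr(m, "onset_row")),
            class = "role_series")
}

#' @export
print.role_series <- function(x, ...) {
  cat(sprintf("<role_series> %s: %d samples averaged over %d reaches\n",
              x$role, length(x$series), x$n_reaches))
  invisible(x)
}

#' @export
plot.role_series <- function(x, ...) {
  fs <- if (is.null(x$fs)) 60 else x$fs
  onset <- if (is.null(x$onset_row)) 1L else x$onset_row
  t <- (seq_along(x$series) - onset) / fs
  graphics::plot(t, x$series, type = "l", xlab = "time from reach onset (s)",
                 ylab = "acceleration (m/s^2)",
                 main = x$role, ...)
  graphics::abline(v = 0, lty = 2, col = "red")
  invisible(x)
}

#' Filter reaches by type
#'
#' `"all"` keeps every unimanual reach; a specific type keeps only that
#' category. An empty subset is an error naming the type.
#'
#' @param reaches Data frame of reach events (from [select_unimanual()]).
#' @param type One of `"all"`, `"grasp"`, `"touch"`, `"unsuccessful"`.
#' @return The filtered reach data frame.
#' @export
collapse_by_type <- function(reaches, type = c("all", "grasp", "touch",
                                               "unsuccessful")) {
  type <- match.arg(type)
  if (type == "all") return(reaches)
  out <- reaches[reaches$category == type, , drop = FALSE]
  if (nrow(out) == 0L) stop("no reaches of type '", type, "'")
  rownames(out) <- NULL
  out
}

#' Build per-role epoch matrices
#'
#' For every reach, assigns limb roles from the reach's hand and extracts one
#' epoch column per role from the corresponding series, keeping the three
#' role matrices column-consistent (a reach skipped for one role is skipped
#' for all).
#'
#' @param series Named list of preprocessed limb magnitude series.
#' @param reaches Data frame of unimanual reach events on the sensor clock.
#' @param pre,post Window extent, seconds.
#' @param fs Sampling rate, Hz.
#' @return Named list of `epoch_matrix` objects for `acting_arm`,
#'   `non_acting_arm` and (when both legs are available) `legs_mean`, with a
#'   shared `skipped` attribute. When a leg sensor is excluded the legs role
#'   is dropped so the arm pair can still be analyzed; a reach whose arm
#'   sensor is excluded is skipped entirely.
#' @export
role_epoch_matrices <- function(series, reaches, pre = 2, post = 2, fs = 60) {
  legs_ok <- !is.null(series$left_leg) && !is.null(series$right_leg)
  roles <- c("acting_arm", "non_acting_arm", if (legs_ok) "legs_mean")
  cols <- stats::setNames(vector("list", length(roles)), roles)
  meta_keep <- list()
  skipped <- character(0)
  if (!legs_ok) skipped <- c(skipped,
    "legs_mean role dropped: a leg sensor is excluded")
  n <- max(vapply(Filter(Negate(is.null), series), length, integer(1)))
  rows <- round((pre + post) * fs)
  pre_s <- round(pre * fs)
  legs_mean <- if (legs_ok) (series$left_leg + series$right_leg) / 2
  for (i in seq_len(nrow(reaches))) {
    hand <- reaches$hand[i]
    acting_lab <- paste0(hand, "_arm")
    non_lab <- paste0(setdiff(c("left", "right"), hand), "_arm")
    if (is.null(series[[acting_lab]]) || is.null(series[[non_lab]])) {
      skipped <- c(skipped, sprintf(
        "onset %.3f s skipped: excluded arm sensor needed for a role",
        reaches$onset[i]))
      next
    }
    rs <- list(acting_arm = series[[acting_lab]],
               non_acting_arm = series[[non_lab]])
    if (legs_ok) rs$legs_mean <- legs_mean
    c0 <- round(reaches$onset[i] * fs)
    lo <- c0 - pre_s
    hi <- lo + rows - 1L
    if (lo < 0L || hi >= n) {
      skipped <- c(skipped, sprintf("onset %.3f s skipped: window outside recording",
                                    reaches$onset[i]))
      next
    }
    for (r in roles) cols[[r]][[length(cols[[r]]) + 1L]] <- rs[[r]][(lo + 1L):(hi + 1L)]
    meta_keep[[length(meta_keep) + 1L]] <- reaches[i, , drop = FALSE]
  }
  if (length(meta_keep) == 0L) stop("no usable reaches after role assignment")
  meta <- do.call(rbind, meta_keep)
  rownames(meta) <- NULL
  out <- lapply(roles, function(r) {
    m <- do.call(cbind, cols[[r]])
    structure(m, fs = fs, pre = pre, post = post, onset_row = pre_s + 1L,
              meta = meta, skipped = skipped,
              class = c("epoch_matrix", class(m)))
  })
  stats::setNames(out, roles)
}
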