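#' Default run configuration
#'
#' Returns the full default configuration for the pipeline, organised in four
#' sections: `preprocessing`, `sync`, `epoching` and `stats`. All tunables of
#' the analysis live here so a run is fully described by one object.
#'
#' Defaults: outlier threshold 150 m/s^2, sensor exclusion above 25% missing,
#' 25 Hz 4th-order low-pass Butterworth, target sampling rate 60 Hz, gravity
#' 9.8 m/s^2, 15 s kick-window pad, median + 3 MAD activity binarization,
#' +/- 5 s lag search, 2 s pre / 2 s post epochs, minimum 4 unimanual reaches
#' per participant, maximum VAR lag 120, alpha 0.05.
#'
#' @return A named nested list of class `kinegc_config`.
#' @export
default_config <- function() {
  cfg <- list(
    preprocessing = list(
      outlier_threshold   = 150,   # m/s^2, per raw axis
      exclusion_threshold = 0.25,  # max missing proportion per axis
      filter_order        = 4,
      filter_cutoff       = 25,    # Hz
      target_fs           = 60,    # Hz
      gravity             = 9.8,   # m/s^2
      zero_phase          = FALSE  # forward-backward filtering (squares gain)
    ),
    sync = list(
      pad       = 15,     # s around first/last kick annotation
      mad_k     = 3,      # binarization threshold: median + k * MAD
      max_lag_s = 5,      # lag search half-width, s
      leg       = "auto"  # or "left_leg" / "right_leg"
    ),
    epoching = list(
      pre         = 2,  # s before reach onset
      post        = 2,  # s after reach onset
      min_reaches = 4   # participant exclusion threshold
    ),
    stats = list(
      max_lag = 120,   # VAR lag-selection search ceiling
      alpha   = 0.05,
      holm    = FALSE  # optional Holm correction of the p column
    )
  )
  class(cfg) <- "kinegc_config"
  cfg
}

config_types <- function() {
  list(
    preprocessing = list(outlier_threshold = "numeric", exclusion_threshold = "numeric",
                         filter_order = "numeric", filter_cutoff = "numeric",
                         target_fs = "numeric", gravity = "numeric",
                         zero_phase = "logical"),
    sync = list(pad = "numeric", mad_k = "numeric", max_lag_s = "numeric",
                leg = "character"),
    epoching = list(pre = "numeric", post = "numeric", min_reaches = "numeric"),
    stats = list(max_lag = "numeric", alpha = "numeric", holm = "logical")
  )
}

validate_config <- function(cfg) {
  types <- config_types()
  extra <- setdiff(names(cfg), names(types))
  if (length(extra)) {
    stop("unknown configuration section(s): ", paste(extra, collapse = ", "))
  }
  for (sec in names(cfg)) {
    keys <- names(cfg[[sec]])
    unknown <- setdiff(keys, names(types[[sec]]))
    if (length(unknown)) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "))
    }
    for (k in keys) {
      v <- cfg[[sec]][[k]]
      want <- types[[sec]][[k]]
      ok <- switch(want,
                   numeric   = is.numeric(v) && length(v) == 1L && is.finite(v),
                   logical   = is.logical(v) && length(v) == 1L && !is.na(v),
                   character = is.character(v) && length(v) == 1L)
      if (!ok) {
        stop("configuration key '", sec, ".", k, "' must be ", want)
      }
    }
  }
  p <- cfg$preprocessing
  if (p$outlier_threshold <= 0) stop("preprocessing.outlier_threshold must be > 0")
  if (p$exclusion_threshold < 0 || p$exclusion_threshold > 1)
    stop("preprocessing.exclusion_threshold must be in [0, 1]")
  if (p$filter_cutoff <= 0) stop("preprocessing.filter_cutoff must be > 0")
  if (p$filter_order < 1) stop("preprocessing.filter_order must be >= 1")
  if (p$target_fs <= 0) stop("preprocessing.target_fs must be > 0")
  if (cfg$sync$pad < 0) stop("sync.pad must be >= 0")
  if (cfg$sync$max_lag_s <= 0) stop("sync.max_lag_s must be > 0")
  if (!(cfg$sync$leg %in% c("auto", "left_leg", "right_leg")))
    stop("sync.leg must be 'auto', 'left_leg' or 'right_leg'")
  if (cfg$epoching$pre <= 0 || cfg$epoching$post <= 0)
    stop("epoching.pre and epoching.post must be > 0")
  if (cfg$stats$max_lag < 1) stop("stats.max_lag must be >= 1")
  if (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1)
    stop("stats.alpha must be in (0, 1)")
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML configuration file, fills every unspecified key with its
#' default (see [default_config()]), rejects unknown sections or keys, and
#' type-checks every value. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration of class `kinegc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("configuration must be a YAML mapping")
  cfg <- default_config()
  types <- config_types()
  extra <- setdiff(names(user), names(types))
  if (length(extra)) {
    stop("unknown configuration section(s): ", paste(extra, collapse = ", "))
  }
  for (sec in names(user)) {
    if (!is.list(user[[sec]]))
      stop("configuration section '", sec, "' must be a mapping")
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
  }
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg A `kinegc_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.kinegc_config <- function(x, ...) {
  cat("kinegc run configuration\n")
  for (sec in names(x)) {
    cat("  ", sec, ":\n", sep = "")
    for (k in names(x[[sec]])) {
      cat("    ", k, " = ", format(x[[sec]][[k]]), "\n", sep = "")
    }
  }
  invisible(x)
}
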