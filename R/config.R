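#' Pipeline configuration
#'
#' Bundles the tunable constants of the contingent analysis. Defaults follow
#' the Hudson River study system: river km 43 (Tappan Zee Bridge) is the
#' designated start/end threshold of a spawning phenology, river km 35 (the
#' NJ-NY border) anchors the series padding, and gaps in the daily position
#' series are filled with a 4-day exponential-weighted moving average.
#'
#' @param entry_exit_threshold_km River kilometre a fish must reach for a day
#'   to count as part of the spawning run; entry/exit dates are the outermost
#'   crossings of this threshold.
#' @param pad_km Constant river kilometre used to pad phenology series to a
#'   common date axis. Must lie below `entry_exit_threshold_km` so padding can
#'   never be mistaken for run presence.
#' @param imputation_window_days Half-width (calendar days, each side) of the
#'   exponential-weighted moving-average imputer.
#' @param n_clusters Number of contingents `k` sought by the k-medoids fit.
#' @param dtw_step_pattern `"symmetric2"` (diagonal steps weigh the local cost
#'   twice; the common default) or `"symmetric1"`.
#' @param dtw_window Optional Sakoe-Chiba band half-width in days; `NULL`
#'   leaves the warp unconstrained.
#' @param censor_window_days A fish whose last detection falls within this
#'   many days of the analysis-period end is right-censored rather than
#'   treated as a death.
#' @param analysis_period Length-2 `Date` vector bounding the mortality
#'   analysis, or `NULL` to use the full data range.
#' @param tz_offset_hours Offset added to UTC timestamps before daily binning
#'   (local civil date); default -5 (US Eastern standard time).
#' @param random_seed Integer seed used wherever the pipeline draws random
#'   numbers (only optional restart modes do).
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$entry_exit_threshold_km
#' @export
pipeline_config <- function(entry_exit_threshold_km = 43,
                            pad_km = 35,
                            imputation_window_days = 4,
                            n_clusters = 2,
                            dtw_step_pattern = c("symmetric2", "symmetric1"),
                            dtw_window = NULL,
                            censor_window_days = 30,
                            analysis_period = NULL,
                            tz_offset_hours = -5,
                            random_seed = 1L) {
  dtw_step_pattern <- match.arg(dtw_step_pattern)
  cfg <- list(
    entry_exit_threshold_km = as.numeric(entry_exit_threshold_km),
    pad_km = as.numeric(pad_km),
    imputation_window_days = as.integer(imputation_window_days),
    n_clusters = as.integer(n_clusters),
    dtw_step_pattern = dtw_step_pattern,
    dtw_window = if (is.null(dtw_window)) NULL else as.integer(dtw_window),
    censor_window_days = as.integer(censor_window_days),
    analysis_period = if (is.null(analysis_period)) NULL else as.Date(analysis_period),
    tz_offset_hours = as.numeric(tz_offset_hours),
    random_seed = as.integer(random_seed)
  )
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    is.finite(cfg$pad_km), is.finite(cfg$entry_exit_threshold_km),
    cfg$imputation_window_days >= 1L,
    cfg$n_clusters >= 1L,
    cfg$censor_window_days >= 0L
  )
  if (cfg$pad_km >= cfg$entry_exit_threshold_km)
    stop("pad_km must be below entry_exit_threshold_km", call. = FALSE)
  if (!is.null(cfg$analysis_period) && length(cfg$analysis_period) != 2L)
    stop("analysis_period must be a length-2 Date vector", call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; absent keys
#' keep their defaults, unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Contingent pipeline configuration\n")
  cat(sprintf("  entry/exit threshold: river km %.1f\n", x$entry_exit_threshold_km))
  cat(sprintf("  padding anchor:       river km %.1f\n", x$pad_km))
  cat(sprintf("  imputation window:    %d d each side (weights 2^-d)\n",
              x$imputation_window_days))
  cat(sprintf("  clusters (k):         %d\n", x$n_clusters))
  cat(sprintf("  DTW step pattern:     %s%s\n", x$dtw_step_pattern,
              if (is.null(x$dtw_window)) "" else sprintf(", band %d d", x$dtw_window)))
  cat(sprintf("  censor window:        %d d\n", x$censor_window_days))
  if (!is.null(x$analysis_period))
    cat(sprintf("  analysis period:      %s to %s\n",
                x$analysis_period[1], x$analysis_period[2]))
  invisible(x)
}
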