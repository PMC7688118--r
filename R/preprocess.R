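#' Mean daily river position of one fish
#'
#' Averages the river-kilometre positions of all detections of a tag on each
#' local calendar date. Detections at receivers without a river kilometre
#' (coastal/shelf arrays) are excluded; an unknown receiver id is an error.
#'
#' @param events Detection data frame for one tag (`timestamp`, `receiver_id`).
#' @param receivers Receiver data frame (`receiver_id`, `river_km`).
#' @param tz_offset_hours Offset applied to UTC timestamps before daily
#'   binning.
#' @return Data frame with `date` and `river_km` (one row per detected day,
#'   sorted), possibly empty.
#' @export
daily_mean_position <- function(events, receivers, tz_offset_hours = -5) {
  unknown <- setdiff(unique(events$receiver_id), receivers$receiver_id)
  if (length(unknown))
    stop("unknown receiver_id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  km <- receivers$river_km[match(events$receiver_id, receivers$receiver_id)]
  keep <- !is.na(km)
  if (!any(keep))
    return(data.frame(date = as.Date(character()), river_km = numeric()))
  dates <- as.Date(events$timestamp[keep] + tz_offset_hours * 3600, tz = "UTC")
  agg <- aggregate(list(river_km = km[keep]), by = list(date = dates), mean)
  agg[order(agg$date), , drop = FALSE]
}

#' Exponential-weighted moving-average gap imputation
#'
#' Fills `NA` values in a daily series with the weighted mean of observed
#' values within `window` days on each side, weight `2^-d` for day-distance
#' `d`. A gap with no observed neighbour inside the window falls back to
#' linear interpolation between the nearest observations (and is reported via
#' a message).
#'
#' @param x Numeric vector on a daily grid, interior `NA`s to fill; the first
#'   and last element must be observed and at least two values observed.
#' @param window Half-width of the window in days (default 4).
#' @return Numeric vector with `NA`s filled; attribute `"imputed"` is a
#'   logical vector marking filled positions.
#' @examples
#' impute_gaps(c(0, NA, NA, 3))  # -> 0 1 2 3
#' @export
impute_gaps <- function(x, window = 4) {
  stopifnot(window >= 1)
  obs <- which(!is.na(x))
  if (length(obs) < 2L && anyNA(x))
    stop("need at least two observed values to impute", call. = FALSE)
  if (anyNA(x) && (is.na(x[1]) || is.na(x[length(x)])))
    stop("leading/trailing gaps are handled by padding, not imputation",
         call. = FALSE)
  out <- x
  miss <- which(is.na(x))
  fallback <- 0L
  for (i in miss) {
    nb <- obs[abs(obs - i) <= window]
    if (length(nb)) {
      w <- 2^(-abs(nb - i))
      out[i] <- sum(w * x[nb]) / sum(w)
    } else {
      lo <- max(obs[obs < i]); hi <- min(obs[obs > i])
      out[i] <- x[lo] + (x[hi] - x[lo]) * (i - lo) / (hi - lo)
      fallback <- fallback + 1L
    }
  }
  if (fallback)
    message(fallback, " value(s) beyond the EWMA window filled by linear ",
            "interpolation")
  attr(out, "imputed") <- seq_along(x) %in% miss
  out
}

#' Dense daily position series for one fish-year
#'
#' Expands a sparse daily-position table onto the full calendar grid between
#' its first and last observed date and imputes interior gaps with
#' [impute_gaps()].
#'
#' @param sparse Data frame from [daily_mean_position()].
#' @param window Imputation window (days).
#' @return Data frame with `date`, `river_km`, `provenance`
#'   (`"observed"`/`"imputed"`).
#' @export
dense_daily_series <- function(sparse, window = 4) {
  if (nrow(sparse) == 0L)
    return(data.frame(date = as.Date(character()), river_km = numeric(),
                      provenance = character()))
  grid <- seq(min(sparse$date), max(sparse$date), by = "day")
  x <- rep(NA_real_, length(grid))
  x[match(sparse$date, grid)] <- sparse$river_km
  filled <- impute_gaps(x, window)
  data.frame(date = grid, river_km = as.numeric(filled),
             provenance = ifelse(attr(filled, "imputed"), "imputed", "observed"),
             stringsAsFactors = FALSE)
}

#' Extract the spawning-run segment of a dense series
#'
#' Entry is the first date at or above the threshold and exit the last such
#' date (outermost crossings); brief dips below the threshold inside the run
#' are retained. A series that never reaches the threshold yields `NULL`
#' (skipped spawning).
#'
#' @param dense Data frame from [dense_daily_series()].
#' @param threshold_km Entry/exit threshold (river km, default 43).
#' @return A list of class `run_segment` (`entry_date`, `exit_date`,
#'   `series`), or `NULL`.
#' @export
extract_run <- function(dense, threshold_km = 43) {
  above <- which(dense$river_km >= threshold_km)
  if (!length(above)) return(NULL)
  i <- min(above); j <- max(above)
  structure(list(entry_date = dense$date[i], exit_date = dense$date[j],
                 series = dense[i:j, , drop = FALSE]),
            class = "run_segment")
}

#' @export
print.run_segment <- function(x, ...) {
  cat(sprintf("Run segment %s to %s (%d d, peak km %.1f)\n",
              x$entry_date, x$exit_date, nrow(x$series),
              max(x$series$river_km)))
  invisible(x)
}

#' Catenate run segments onto a common padded date axis
#'
#' All segments of a cohort-year are placed on the union date span
#' `[min entry, max exit]`; days outside a fish's own run are padded with the
#' constant `pad_km` (a point down-estuary of every receiver), which preserves
#' calendar information and penalizes alignment of runs far apart in time.
#'
#' @param segments Named list of `run_segment`s (names = tag ids).
#' @param pad_km Padding constant (river km, default 35).
#' @return A `phenology_matrix`: numeric matrix (fish x day) with the date
#'   axis in attribute `"dates"` and a same-shape provenance matrix
#'   (`"observed"`/`"imputed"`/`"pad"`) in attribute `"provenance"`.
#' @export
catenate_pad <- function(segments, pad_km = 35) {
  segments <- segments[!vapply(segments, is.null, logical(1))]
  if (!length(segments)) stop("no run segments to catenate", call. = FALSE)
  axis <- seq(min(as.Date(sapply(segments, `[[`, "entry_date"),
                          origin = "1970-01-01")),
              max(as.Date(sapply(segments, `[[`, "exit_date"),
                          origin = "1970-01-01")), by = "day")
  n <- length(segments); m <- length(axis)
  X <- matrix(pad_km, n, m, dimnames = list(names(segments), as.character(axis)))
  P <- matrix("pad", n, m)
  for (i in seq_len(n)) {
    s <- segments[[i]]$series
    idx <- match(s$date, axis)
    X[i, idx] <- s$river_km
    P[i, idx] <- s$provenance
  }
  structure(X, dates = axis, provenance = P, pad_km = pad_km,
            class = c("phenology_matrix", "matrix"))
}

#' @export
print.phenology_matrix <- function(x, ...) {
  d <- attr(x, "dates")
  cat(sprintf("Phenology matrix: %d series x %d days (%s to %s), pad km %.1f\n",
              nrow(x), ncol(x), min(d), max(d), attr(x, "pad_km")))
  invisible(x)
}

#' Daily phenology series for every fish-year in a detection log
#'
#' Runs the preprocessing chain (daily mean position, gap imputation, run
#' extraction) per fish and run-year and reports, for every tag, whether it
#' was assigned a run, skipped spawning that year, or was excluded for
#' insufficient data.
#'
#' @param detections Detection data frame ([read_detections()] format).
#' @param receivers Receiver data frame.
#' @param config A [pipeline_config()].
#' @param years Years to process (default: all years present).
#' @return List with `segments` (nested list `[[year]][[tag_id]]` of
#'   `run_segment`s) and `status` (data frame `tag_id`, `year`, `status`,
#'   `reason`).
#' @export
build_segments <- function(detections, receivers, config = pipeline_config(),
                           years = NULL) {
  tz <- config$tz_offset_hours
  all_dates <- as.Date(detections$timestamp + tz * 3600, tz = "UTC")
  yr <- as.integer(format(all_dates, "%Y"))
  if (is.null(years)) years <- sort(unique(yr))
  segments <- list(); status <- list()
  for (y in years) {
    segs <- list()
    in_year <- yr == y
    for (tag in sort(unique(detections$tag_id[in_year]))) {
      ev <- detections[in_year & detections$tag_id == tag, , drop = FALSE]
      sparse <- daily_mean_position(ev, receivers, tz)
      if (nrow(sparse) < 2L) {
        status[[length(status) + 1L]] <- data.frame(
          tag_id = tag, year = y, status = "excluded",
          reason = "fewer than 2 in-river detection days")
        next
      }
      dense <- dense_daily_series(sparse, config$imputation_window_days)
      seg <- extract_run(dense, config$entry_exit_threshold_km)
      if (is.null(seg)) {
        status[[length(status) + 1L]] <- data.frame(
          tag_id = tag, year = y, status = "skipped",
          reason = "never crossed the entry threshold")
      } else {
        segs[[tag]] <- seg
        status[[length(status) + 1L]] <- data.frame(
          tag_id = tag, year = y, status = "assigned", reason = "")
      }
    }
    segments[[as.character(y)]] <- segs
  }
  list(segments = segments, status = do.call(rbind, status))
}
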