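#' Cumulative incidence curve of river entries
#'
#' @param entry_dates `Date` vector (one per fish).
#' @return Object of class `incidence_curve`: data frame `date`,
#'   `cumulative` spanning first to last entry; the final value equals the
#'   group size.
#' @export
incidence_curve <- function(entry_dates) {
  entry_dates <- as.Date(entry_dates)
  if (!length(entry_dates)) stop("empty group", call. = FALSE)
  axis <- seq(min(entry_dates), max(entry_dates), by = "day")
  cum <- vapply(axis, function(d) sum(entry_dates <= d), integer(1))
  structure(data.frame(date = axis, cumulative = cum),
            class = c("incidence_curve", "data.frame"))
}

#' Date of 50% incidence
#'
#' First date on which cumulative incidence reaches half the group's eventual
#' total, `ceiling(n / 2)`.
#'
#' @param curve An [incidence_curve()].
#' @return A `Date`.
#' @export
incidence_50_date <- function(curve) {
  n <- curve$cumulative[nrow(curve)]
  curve$date[which(curve$cumulative >= ceiling(n / 2))[1]]
}

#' Temperature experienced on a date
#'
#' Exact lookup in a gap-free daily environmental series.
#'
#' @param env Environmental data frame (`date`, `water_temp_C`).
#' @param date A `Date` within the series range.
#' @return Water temperature in degC.
#' @export
temperature_at <- function(env, date) {
  date <- as.Date(date)
  i <- match(date, env$date)
  if (anyNA(i))
    stop("date outside environmental series range: ",
         paste(date[is.na(i)], collapse = ", "), call. = FALSE)
  env$water_temp_C[i]
}

# median on ordinal days: even n takes the earlier of the two central days
median_date <- function(dates) {
  d <- sort(as.numeric(as.Date(dates)))
  n <- length(d)
  as.Date(if (n %% 2L == 1L) d[(n + 1L) %/% 2L]
          else floor((d[n %/% 2L] + d[n %/% 2L + 1L]) / 2),
          origin = "1970-01-01")
}

#' Run-timing statistics per contingent
#'
#' First/median/last entry and exit dates, the 50%-incidence date and (when
#' an environmental series is supplied) the water temperature experienced on
#' that date, for each contingent group of run segments. Medians are computed
#' on ordinal day numbers; with an even group size the mean of the two
#' central days is rounded down to the earlier day.
#'
#' @param segments Named list of `run_segment`s (names = tag ids).
#' @param groups Named character vector mapping tag ids to contingent labels.
#' @param env Optional environmental data frame for the temperature lookup.
#' @param year Optional year recorded in the output.
#' @return Data frame, one row per contingent, with columns `contingent`,
#'   `year`, `n_fish`, `first_entry`, `median_entry`, `last_entry`,
#'   `first_exit`, `median_exit`, `last_exit`, `date_50pct`, `temp_50pct_C`.
#' @export
run_stats <- function(segments, groups, env = NULL, year = NA_integer_) {
  segments <- segments[!vapply(segments, is.null, logical(1))]
  tags <- intersect(names(segments), names(groups))
  if (!length(tags)) stop("empty group: no segments match groups", call. = FALSE)
  rows <- lapply(sort(unique(groups[tags])), function(g) {
    gt <- tags[groups[tags] == g]
    entries <- as.Date(sapply(segments[gt], `[[`, "entry_date"),
                       origin = "1970-01-01")
    exits <- as.Date(sapply(segments[gt], `[[`, "exit_date"),
                     origin = "1970-01-01")
    d50 <- incidence_50_date(incidence_curve(entries))
    data.frame(
      contingent = g, year = year, n_fish = length(gt),
      first_entry = min(entries), median_entry = median_date(entries),
      last_entry = max(entries),
      first_exit = min(exits), median_exit = median_date(exits),
      last_exit = max(exits),
      date_50pct = d50,
      temp_50pct_C = if (is.null(env)) NA_real_ else temperature_at(env, d50),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
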