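#' Read an acoustic detection log
#'
#' Expects a UTF-8 CSV with header columns `timestamp`, `tag_id`,
#' `receiver_id` (any order). Timestamps are interpreted as UTC and accepted
#' as `"YYYY-MM-DD HH:MM:SS"`, `"YYYY-MM-DDTHH:MM:SS"` or a bare date.
#'
#' @param path CSV file path.
#' @return A data frame with columns `tag_id` (character), `timestamp`
#'   (`POSIXct`, UTC) and `receiver_id` (character), sorted by
#'   (`tag_id`, `timestamp`).
#' @export
read_detections <- function(path) {
  df <- read_input_csv(path, c("timestamp", "tag_id", "receiver_id"))
  if (nrow(df) == 0L)
    return(data.frame(tag_id = character(), timestamp = as_utc(character()),
                      receiver_id = character(), stringsAsFactors = FALSE))
  ts <- as_utc(df$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts)) + 1L  # +1 for the header row
    stop(sprintf("unparseable timestamp on line(s): %s of %s",
                 paste(bad, collapse = ", "), path), call. = FALSE)
  }
  if (any(!nzchar(df$tag_id)) || any(!nzchar(df$receiver_id))) {
    bad <- which(!nzchar(df$tag_id) | !nzchar(df$receiver_id)) + 1L
    stop(sprintf("empty tag_id/receiver_id on line(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(tag_id = as.character(df$tag_id), timestamp = ts,
                    receiver_id = as.character(df$receiver_id),
                    stringsAsFactors = FALSE)
  out <- out[order(out$tag_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read receiver (station) metadata
#'
#' Expects columns `receiver_id`, `river_km` and optionally `region`. River
#' receivers carry a river kilometre; shelf/coastal array receivers may leave
#' `river_km` empty and give a `region` code instead.
#'
#' @param path CSV file path.
#' @return Data frame with `receiver_id`, `river_km` (numeric, `NA` allowed
#'   for non-river arrays) and `region` (character, `NA` when absent).
#' @export
read_receivers <- function(path) {
  df <- read_input_csv(path, c("receiver_id", "river_km"), optional = "region")
  df$receiver_id <- as.character(df$receiver_id)
  if (anyDuplicated(df$receiver_id))
    stop("duplicate receiver_id: ",
         paste(unique(df$receiver_id[duplicated(df$receiver_id)]), collapse = ", "),
         call. = FALSE)
  df$river_km <- suppressWarnings(as.numeric(df$river_km))
  if (any(is.infinite(df$river_km)) || any(df$river_km < 0, na.rm = TRUE))
    stop("river_km must be finite and non-negative", call. = FALSE)
  if (is.null(df$region)) df$region <- rep(NA_character_, nrow(df))
  df$region <- as.character(df$region)
  df$region[!nzchar(df$region) | is.na(df$region)] <- NA_character_
  df[, c("receiver_id", "river_km", "region")]
}

#' Read tagged-fish metadata
#'
#' Expects columns `tag_id`, `tagging_date`, `tagging_reach` (`lower` or
#' `upper`), `length_cm`, `weight_kg`, `sex` (`F`, `M`, or `unknown`). An
#' unrecognised sex code is coerced to `"unknown"` with a warning.
#'
#' @param path CSV file path.
#' @return Validated data frame, one row per tagged fish.
#' @export
read_fish <- function(path) {
  df <- read_input_csv(path, c("tag_id", "tagging_date", "tagging_reach",
                               "length_cm", "weight_kg", "sex"))
  df$tag_id <- as.character(df$tag_id)
  if (anyDuplicated(df$tag_id))
    stop("duplicate tag_id in fish metadata", call. = FALSE)
  df$tagging_date <- as.Date(df$tagging_date)
  if (anyNA(df$tagging_date)) stop("unparseable tagging_date", call. = FALSE)
  if (!all(df$tagging_reach %in% c("lower", "upper")))
    stop("tagging_reach must be 'lower' or 'upper'", call. = FALSE)
  df$length_cm <- suppressWarnings(as.numeric(df$length_cm))
  df$weight_kg <- suppressWarnings(as.numeric(df$weight_kg))
  if (any(df$length_cm <= 0 | df$weight_kg <= 0, na.rm = TRUE))
    stop("length_cm and weight_kg must be positive when present", call. = FALSE)
  df$sex <- as.character(df$sex)
  bad <- !(df$sex %in% c("F", "M", "unknown"))
  if (any(bad)) {
    warning(sprintf("%d fish with unrecognised sex coerced to 'unknown'",
                    sum(bad)), call. = FALSE)
    df$sex[bad] <- "unknown"
  }
  df
}

#' Read a daily environmental series
#'
#' Expects columns `date`, `water_temp_C`, `discharge_m3s`. Dates must be
#' strictly increasing with no missing calendar day inside the range.
#'
#' @param path CSV file path.
#' @return Data frame with `date` (`Date`), `water_temp_C`, `discharge_m3s`.
#' @export
read_environment <- function(path) {
  df <- read_input_csv(path, c("date", "water_temp_C", "discharge_m3s"))
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable date in environment file", call. = FALSE)
  if (is.unsorted(df$date, strictly = TRUE))
    stop("environment dates must be strictly increasing", call. = FALSE)
  full <- seq(df$date[1], df$date[nrow(df)], by = "day")
  miss <- setdiff(as.character(full), as.character(df$date))
  if (length(miss))
    stop("environment series has a gap; first missing date: ", miss[1],
         call. = FALSE)
  df$water_temp_C <- as.numeric(df$water_temp_C)
  df$discharge_m3s <- as.numeric(df$discharge_m3s)
  df
}

# shared CSV reader: header check + raw character frame
read_input_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df[, intersect(c(required, optional), names(df)), drop = FALSE]
}

# parse timestamps, returning NA (not an error) for unrecognised strings
as_utc <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

SCHEMA_VERSION <- "runcontingent-table v1"

#' Write an output table with a schema header
#'
#' Tables are plain CSV preceded by a single comment line naming the table
#' and schema version, so written outputs are self-describing and can be
#' re-read with [read_table()].
#'
#' @param df Data frame.
#' @param path Destination file.
#' @param name Table name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, name = deparse(substitute(df))) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", SCHEMA_VERSION, name), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Re-read a table written by [write_table()]
#'
#' Columns named `date` or ending in `_date` are restored to `Date`;
#' `timestamp` columns to UTC `POSIXct`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, paste0("# ", SCHEMA_VERSION)))
    stop("not a recognised output table (schema header missing): ", path,
         call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (nm in names(df)) {
    v <- df[[nm]]
    if (nm == "timestamp") {
      df[[nm]] <- as_utc(v)
    } else if (is.character(v) && length(v) &&
               all(grepl("^\\d{4}-\\d{2}-\\d{2}$", v[!is.na(v)]))) {
      df[[nm]] <- as.Date(v)   # ISO date column (entry/exit dates etc.)
    }
  }
  df
}
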