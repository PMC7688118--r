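#' Build survival records from a detection log
#'
#' One record per grouped fish: time runs from the fish's origin (typically
#' its run-exit date) to its last detection inside the analysis period. Last
#' detection is read as the assumed loss from the sample (death) unless it
#' falls within `censor_window_days` of the period end, in which case the
#' fish is right-censored at the period end. Fish without detections after
#' their origin inside the period are dropped with a message.
#'
#' @param detections Detection data frame (all arrays, river and shelf).
#' @param groups Named character vector: tag id -> group (contingent).
#' @param origin Named `Date` vector of per-fish origins, or one common date.
#' @param analysis_period Length-2 `Date` vector.
#' @param censor_window_days Width of the terminal censoring window (days).
#' @param tz_offset_hours Offset for daily binning of timestamps.
#' @return Data frame with `tag_id`, `group`, `origin_date`, `end_date`,
#'   `time_days`, `event`.
#' @export
build_records <- function(detections, groups, origin, analysis_period,
                          censor_window_days = 30, tz_offset_hours = -5) {
  period <- as.Date(analysis_period)
  stopifnot(length(period) == 2L, period[1] <= period[2])
  tags <- names(groups)
  if (length(origin) == 1L && is.null(names(origin)))
    origin <- setNames(rep(as.Date(origin), length(tags)), tags)
  origin <- as.Date(origin)
  det_date <- as.Date(detections$timestamp + tz_offset_hours * 3600, tz = "UTC")
  rows <- list(); dropped <- 0L
  for (tag in tags) {
    o <- origin[[tag]]
    if (is.na(o)) { dropped <- dropped + 1L; next }
    dd <- det_date[detections$tag_id == tag]
    dd <- dd[dd >= o & dd <= period[2]]
    if (!length(dd)) { dropped <- dropped + 1L; next }
    last <- max(dd)
    censored <- last >= period[2] - censor_window_days
    end <- if (censored) period[2] else last
    rows[[length(rows) + 1L]] <- data.frame(
      tag_id = tag, group = groups[[tag]], origin_date = o, end_date = end,
      time_days = as.numeric(end - o), event = !censored,
      stringsAsFactors = FALSE)
  }
  if (dropped)
    message(dropped, " fish without usable detections in the analysis period",
            " were excluded from the survival records")
  if (!length(rows)) stop("no usable survival records", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Instantaneous daily loss rate Z from extant counts
#'
#' The number of extant (at-large) individuals is summed for each date,
#' log-transformed, and regressed against days elapsed by ordinary least
#' squares; `Z` is the negative slope (units d^-1). Dates with zero extant
#' individuals are excluded (log undefined).
#'
#' @param x Either a survival-record data frame from [build_records()] (the
#'   daily extant count is then the number of fish whose `end_date` is on or
#'   after each date of the period) or a data frame with columns `day` (or
#'   `date`) and `count`.
#' @param period Optional length-2 `Date` vector restricting the fit (records
#'   input only).
#' @return Object of class `loss_rate_fit`: `Z`, `intercept`, `r_squared`,
#'   `n_days`, and the underlying `lm` fit.
#' @export
loss_rate <- function(x, period = NULL) {
  if (all(c("count", "day") %in% names(x))) {
    df <- data.frame(day = as.numeric(x$day), count = as.numeric(x$count))
  } else if (all(c("count", "date") %in% names(x))) {
    df <- data.frame(day = as.numeric(as.Date(x$date) - min(as.Date(x$date))),
                     count = as.numeric(x$count))
  } else if (all(c("origin_date", "end_date") %in% names(x))) {
    if (is.null(period))
      period <- c(min(x$origin_date), max(x$end_date))
    period <- as.Date(period)
    axis <- seq(period[1], period[2], by = "day")
    count <- vapply(axis, function(d)
      sum(x$origin_date <= d & x$end_date >= d), numeric(1))
    df <- data.frame(day = as.numeric(axis - axis[1]), count = count)
  } else {
    stop("x must be survival records or a day/count data frame", call. = FALSE)
  }
  df <- df[df$count > 0, , drop = FALSE]
  if (nrow(df) < 3L)
    stop("need at least 3 dates with positive counts", call. = FALSE)
  fit <- lm(log(count) ~ day, data = df)
  y <- log(df$count)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(Z = -unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = r2, n_days = nrow(df), fit = fit),
            class = "loss_rate_fit")
}

#' @export
print.loss_rate_fit <- function(x, ...) {
  cat(sprintf("Instantaneous loss rate Z = %.3g d^-1 (r^2 = %.3f, %d days)\n",
              x$Z, x$r_squared, x$n_days))
  invisible(x)
}

#' @export
coef.loss_rate_fit <- function(object, ...) {
  c(Z = object$Z, intercept = object$intercept)
}

#' Kaplan-Meier survival curve with Greenwood standard errors
#'
#' Product-limit estimate over the distinct event times, with Greenwood's
#' variance formula and pointwise normal-approximation 95% confidence
#' limits (clamped to [0, 1]).
#'
#' @param time Numeric follow-up times, or a record data frame with
#'   `time_days` and `event` columns.
#' @param event Logical/0-1 event indicator (TRUE = death), when `time` is a
#'   vector.
#' @return Object of class `km_curve`: data frame-like list with `time`,
#'   `n_risk`, `n_event`, `surv`, `se`, `lower`, `upper`, plus `n` (cohort
#'   size).
#' @export
kaplan_meier <- function(time, event = NULL) {
  if (is.data.frame(time)) { event <- time$event; time <- time$time_days }
  stopifnot(length(time) == length(event), length(time) >= 1L)
  event <- as.logical(event)
  et <- sort(unique(time[event]))
  n <- length(time)
  if (!length(et)) {
    curve <- data.frame(time = numeric(), n_risk = numeric(),
                        n_event = numeric(), surv = numeric(), se = numeric(),
                        lower = numeric(), upper = numeric())
    return(structure(list(curve = curve, n = n), class = "km_curve"))
  }
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), Inf))
  se <- ifelse(surv > 0, surv * sqrt(gw), 0)  # S = 0: variance degenerate
  z <- qnorm(0.975)
  curve <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                      surv = surv, se = se,
                      lower = pmax(0, surv - z * se),
                      upper = pmin(1, surv + z * se))
  structure(list(curve = curve, n = n), class = "km_curve")
}

#' Survival probability (and SE) at a time point
#'
#' @param km A [kaplan_meier()] curve.
#' @param t Time at which to evaluate the step function.
#' @return Named vector `c(surv, se)`.
#' @export
km_at <- function(km, t) {
  cv <- km$curve
  i <- findInterval(t, cv$time)
  if (i == 0L) c(surv = 1, se = 0) else c(surv = cv$surv[i], se = cv$se[i])
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event time(s)\n",
              x$n, nrow(x$curve)))
  if (nrow(x$curve)) {
    last <- x$curve[nrow(x$curve), ]
    cat(sprintf("  final S = %.3f (SE %.3f) at t = %g\n",
                last$surv, last$se, last$time))
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "days", ylab = "survival", ...) {
  cv <- x$curve
  t <- c(0, rep(cv$time, each = 2))
  s <- c(1, 1, rep(cv$surv, each = 2)[-(2 * nrow(cv))])
  plot(t, s, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  lines(cv$time, cv$lower, lty = 3); lines(cv$time, cv$upper, lty = 3)
  invisible(x)
}

#' Weighted log-rank test for two groups
#'
#' At each distinct pooled event time the observed minus expected deaths in
#' group A are weighted and summed; the statistic is
#' `(sum w (dA - E))^2 / sum w^2 V` with hypergeometric mean and variance,
#' referred to chi-square with 1 df. Weight schemes: `"logrank"` (`w = 1`),
#' `"gehan"` (`w = n` at risk), `"peto-peto"` (`w = S~(t)`, the modified
#' pooled survival estimate `prod(1 - d_i / (n_i + 1))`, which emphasizes
#' early differences - the Peto & Peto modification of the Gehan-Wilcoxon
#' test).
#'
#' @param records_a,records_b Record data frames with `time_days`, `event`.
#' @param weights Weight scheme.
#' @return Object of class `two_group_test`: `statistic`, `df`, `p_value`,
#'   `weights`, `n`.
#' @export
weighted_logrank <- function(records_a, records_b,
                             weights = c("peto-peto", "logrank", "gehan")) {
  weights <- match.arg(weights)
  ta <- records_a$time_days; ea <- as.logical(records_a$event)
  tb <- records_b$time_days; eb <- as.logical(records_b$event)
  time <- c(ta, tb); event <- c(ea, eb)
  grp <- rep(c(TRUE, FALSE), c(length(ta), length(tb)))
  if (!any(event)) stop("no events in either group", call. = FALSE)
  et <- sort(unique(time[event]))
  nj <- vapply(et, function(t) sum(time >= t), numeric(1))
  dj <- vapply(et, function(t) sum(time == t & event), numeric(1))
  naj <- vapply(et, function(t) sum(time >= t & grp), numeric(1))
  daj <- vapply(et, function(t) sum(time == t & event & grp), numeric(1))
  e <- dj * naj / nj
  v <- ifelse(nj > 1,
              dj * (naj / nj) * (1 - naj / nj) * (nj - dj) / (nj - 1), 0)
  w <- switch(weights,
              "logrank" = rep(1, length(et)),
              "gehan" = nj,
              "peto-peto" = cumprod(1 - dj / (nj + 1)))
  denom <- sum(w^2 * v)
  stat <- if (denom > 0) sum(w * (daj - e))^2 / denom else 0
  structure(list(statistic = stat, df = 1L,
                 p_value = pchisq(stat, 1L, lower.tail = FALSE),
                 weights = weights, n = length(time)),
            class = "two_group_test")
}

#' @export
print.two_group_test <- function(x, ...) {
  lab <- switch(x$weights,
                "peto-peto" = "Peto & Peto modified Gehan-Wilcoxon",
                "logrank" = "log-rank", "gehan" = "Gehan-Wilcoxon")
  cat(sprintf("%s test: chi-square = %.4g on %d df, p = %.4g (n = %d)\n",
              lab, x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}
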