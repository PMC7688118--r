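#' Run the full contingent analysis pipeline
#'
#' Orchestrates the whole analysis on validated inputs: detections are
#' reduced to daily phenology series per fish and run-year, the first year's
#' cohort is clustered into contingents by DTW k-medoids, later years are
#' classified onto the fitted centroids, cross-year persistence is
#' tabulated and tested, run-timing statistics are computed per
#' contingent-year, and post-run attrition is analyzed (loss rates,
#' Kaplan-Meier curves, between-contingent weighted log-rank test) using the
#' first-year contingent labels throughout, with each run-year's cohort
#' followed from its own run exit.
#'
#' @param detections Detection data frame ([read_detections()] format).
#' @param receivers Receiver data frame ([read_receivers()] format).
#' @param fish Optional tagged-fish metadata (carried into the report).
#' @param environment Optional daily environmental series (enables the
#'   experienced-temperature lookups).
#' @param config A [pipeline_config()].
#' @return Object of class `contingent_report`: the fitted
#'   `contingent_cluster` model plus output tables (`series`, `assignments`,
#'   `crossclass`, `phenology`, `survival`, `km_curves`, `tests`,
#'   `fish_status`) and a run log.
#' @export
run_pipeline <- function(detections, receivers, fish = NULL,
                         environment = NULL, config = pipeline_config()) {
  set.seed(config$random_seed)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  bs <- build_segments(detections, receivers, config)
  years <- as.integer(names(bs$segments)[vapply(bs$segments, length,
                                                integer(1)) > 0])
  if (!length(years))
    stop("empty cohort: no fish passes the run-detection criteria",
         call. = FALSE)
  y1 <- years[1]
  segs1 <- bs$segments[[as.character(y1)]]
  if (length(segs1) < config$n_clusters)
    stop("empty cohort: fewer completing fish than clusters in year ", y1,
         call. = FALSE)
  note("run segments: %s",
       paste(sprintf("%d fish in %d", vapply(bs$segments, length, integer(1)),
                     as.integer(names(bs$segments))), collapse = ", "))

  X1 <- catenate_pad(segs1, config$pad_km)
  model <- contingent_cluster(X1, k = config$n_clusters,
                              step_pattern = config$dtw_step_pattern,
                              window = config$dtw_window)
  note("clustered %d series of %d days into k = %d (cost %.4g)",
       nrow(X1), ncol(X1), config$n_clusters, model$cost)

  assignments <- data.frame(
    tag_id = names(model$assignment), year = y1,
    cluster = unname(model$assignment),
    contingent = unname(model$contingent),
    distance = model$diss[cbind(seq_along(model$assignment),
                                model$medoids[model$assignment])],
    tie = FALSE, stringsAsFactors = FALSE)
  labels_by_year <- list()
  labels_by_year[[as.character(y1)]] <- model$contingent

  for (y in years[-1]) {
    segs <- bs$segments[[as.character(y)]]
    pred <- predict(model, segs)
    pred$year <- y
    assignments <- rbind(assignments,
                         pred[, c("tag_id", "year", "cluster", "contingent",
                                  "distance", "tie")])
    labels_by_year[[as.character(y)]] <-
      setNames(pred$contingent, pred$tag_id)
    note("classified %d series from %d onto the %d centroids",
         nrow(pred), y, model$k)
  }

  crossclass <- NULL
  if (length(years) >= 2L) {
    crossclass <- tryCatch(
      cross_classify(labels_by_year[[1L]], labels_by_year[[2L]]),
      error = function(e) { note("cross-classification skipped: %s",
                                 conditionMessage(e)); NULL })
    if (!is.null(crossclass))
      note("cross-year concordance %.0f%% over %d shared fish",
           100 * crossclass$concordance, crossclass$n_shared)
  }

  series <- do.call(rbind, lapply(years, function(y) {
    X <- catenate_pad(bs$segments[[as.character(y)]], config$pad_km)
    P <- attr(X, "provenance"); dts <- attr(X, "dates")
    data.frame(tag_id = rep(rownames(X), each = ncol(X)), year = y,
               date = rep(dts, times = nrow(X)),
               river_km = round(as.numeric(t(unclass(X))), 1),
               provenance = as.character(t(P)), stringsAsFactors = FALSE)
  }))

  phenology <- do.call(rbind, lapply(years, function(y)
    run_stats(bs$segments[[as.character(y)]], labels_by_year[[as.character(y)]],
              env = environment, year = y)))

  # --- survival, grouped by the first-year contingent labels ---
  det_dates <- as.Date(detections$timestamp + config$tz_offset_hours * 3600,
                       tz = "UTC")
  period <- if (!is.null(config$analysis_period)) config$analysis_period else
    c(min(as.Date(sapply(segs1, `[[`, "exit_date"), origin = "1970-01-01")),
      max(det_dates))
  groups1 <- labels_by_year[[1L]]
  survival_tbl <- NULL; km_tbl <- NULL; tests_tbl <- NULL
  for (y in years) {
    segs <- bs$segments[[as.character(y)]]
    tags <- intersect(names(segs), names(groups1))
    skipped <- setdiff(names(segs), names(groups1))
    if (length(skipped))
      note("%d fish running in %d lack a year-%d label; excluded from survival",
           length(skipped), y, y1)
    if (length(tags) < 2L) next
    origin <- setNames(as.Date(sapply(segs[tags], `[[`, "exit_date"),
                               origin = "1970-01-01"), tags)
    next_y <- years[years > y]
    end_y <- if (length(next_y))
      min(period[2], as.Date(sprintf("%d-03-15", next_y[1]))) else period[2]
    rec <- tryCatch(
      build_records(detections, groups1[tags], origin,
                    c(period[1], end_y), config$censor_window_days,
                    config$tz_offset_hours),
      error = function(e) { note("survival records skipped for %d: %s", y,
                                 conditionMessage(e)); NULL })
    if (is.null(rec)) next
    rec$year <- y
    survival_tbl <- rbind(survival_tbl,
                          rec[, c("year", "tag_id", "group", "origin_date",
                                  "end_date", "time_days", "event")])
    for (g in sort(unique(rec$group))) {
      km <- kaplan_meier(rec[rec$group == g, ])
      if (nrow(km$curve))
        km_tbl <- rbind(km_tbl, cbind(year = y, contingent = g, km$curve))
      zf <- tryCatch(loss_rate(rec[rec$group == g, ]),
                     error = function(e) NULL)
      if (!is.null(zf))
        note("loss rate %d/%s: Z = %.3g d^-1 (r^2 %.2f)", y, g, zf$Z,
             zf$r_squared)
    }
    gl <- sort(unique(rec$group))
    if (length(gl) == 2L) {
      tst <- tryCatch(
        weighted_logrank(rec[rec$group == gl[1], ], rec[rec$group == gl[2], ]),
        error = function(e) NULL)
      if (!is.null(tst))
        tests_tbl <- rbind(tests_tbl, data.frame(
          year = y, groups = paste(gl, collapse = " vs "),
          weights = tst$weights, statistic = tst$statistic, df = tst$df,
          p_value = tst$p_value, stringsAsFactors = FALSE))
    }
  }

  status <- bs$status
  crossclass_tbl <- if (is.null(crossclass)) NULL else {
    cells <- as.data.frame(crossclass$table, stringsAsFactors = FALSE)
    names(cells) <- c("label_year1", "label_year2", "n")
    cells$concordance <- crossclass$concordance
    cells$statistic <- crossclass$statistic
    cells$df <- crossclass$df
    cells$p_value <- crossclass$p_value
    cells
  }
  out <- list(model = model, years = years,
              tables = list(series = series, assignments = assignments,
                            crossclass = crossclass_tbl,
                            phenology = phenology, survival = survival_tbl,
                            km_curves = km_tbl, tests = tests_tbl,
                            fish_status = status),
              crossclass = crossclass, fish = fish, log = log,
              config = config)
  class(out) <- "contingent_report"
  out
}

#' @export
print.contingent_report <- function(x, ...) {
  cat("Contingent analysis report\n")
  cat(sprintf("  years: %s\n", paste(x$years, collapse = ", ")))
  print(x$model)
  if (!is.null(x$crossclass)) print(x$crossclass)
  if (!is.null(x$tables$tests)) {
    cat("Between-contingent survival tests:\n")
    print(x$tables$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Write a report's tables to a directory
#'
#' Writes every non-empty output table as a schema-versioned CSV
#' (`series.csv`, `assignments.csv`, `crossclass.csv`, `phenology.csv`,
#' `survival.csv`, `km_curves.csv`, `tests.csv`, `fish_status.csv`) plus a
#' plain-text run log.
#'
#' @param report A `contingent_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables)) {
    tb <- report$tables[[nm]]
    if (!is.null(tb) && nrow(tb))
      write_table(tb, file.path(dir, paste0(nm, ".csv")), nm)
  }
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
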