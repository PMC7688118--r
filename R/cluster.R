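#' k-medoids (PAM) on a precomputed dissimilarity matrix
#'
#' Deterministic partitioning around medoids: greedy BUILD initialization
#' followed by SWAP steps applied while some (medoid, non-medoid) exchange
#' reduces the total cost, ties broken by lowest index. Because a single
#' BUILD+SWAP descent can stall in a local optimum, the descent is restarted
#' deterministically from every possible first medoid and the lowest-cost
#' solution kept. The objective is the sum over points of the dissimilarity
#' to their nearest medoid.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of clusters, `1 <= k <= nrow(d)`.
#' @return List with `medoids` (indices), `assignment` (nearest-medoid
#'   cluster number per point), `cost` (total within-cluster cost) and
#'   `iterations` (SWAP steps taken by the winning descent).
#' @export
pam_cluster <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k > n) stop("k exceeds the number of series", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0))
    stop("dissimilarity matrix must be symmetric with zero diagonal",
         call. = FALSE)

  cols <- lapply(seq_len(n), function(j) d[, j])
  total_cost <- function(med) sum(Reduce(pmin, cols[med]))

  descend <- function(first) {
    # BUILD: greedy additions from the given first medoid
    med <- first
    while (length(med) < k) {
      cand <- setdiff(seq_len(n), med)
      costs <- vapply(cand, function(h) total_cost(c(med, h)), numeric(1))
      med <- c(med, cand[which.min(costs)])
    }
    cost <- total_cost(med)
    # SWAP: best strictly improving exchange, repeated to convergence
    iter <- 0L
    repeat {
      best <- cost; best_swap <- NULL
      for (mi in seq_along(med)) {
        for (h in setdiff(seq_len(n), med)) {
          trial <- med; trial[mi] <- h
          ct <- total_cost(trial)
          if (ct < best - 1e-12) { best <- ct; best_swap <- c(mi, h) }
        }
      }
      if (is.null(best_swap)) break
      med[best_swap[1]] <- best_swap[2]
      cost <- best
      iter <- iter + 1L
    }
    list(med = med, cost = cost, iter = iter)
  }

  runs <- lapply(seq_len(n), descend)
  win <- runs[[which.min(vapply(runs, `[[`, numeric(1), "cost"))]]
  med <- sort(win$med)
  assignment <- apply(d[, med, drop = FALSE], 1L, which.min)
  list(medoids = med, assignment = as.integer(assignment), cost = win$cost,
       iterations = win$iter)
}

#' Fit a contingent model by DTW k-medoids clustering
#'
#' The central fit of the package: phenology series (rows of a padded
#' [catenate_pad()] matrix) are clustered by PAM under a dynamic time warping
#' dissimilarity, and the medoid series of each cluster is extracted as its
#' centroid. With `k = 2` clusters are labelled `"upper"`/`"lower"` by the
#' peak river kilometre of their centroid; otherwise `"C1"..."Ck"`.
#'
#' @param x A `phenology_matrix` from [catenate_pad()] (or any matrix of
#'   equal-length series in rows).
#' @param k Number of contingents sought (default 2).
#' @inheritParams dtw_distance
#' @param diss Optional precomputed dissimilarity matrix (skips the DTW
#'   computation).
#' @return Object of class `contingent_cluster` with elements `k`, `diss`,
#'   `medoids`, `assignment` (named cluster index), `contingent` (named
#'   label), `labels` (per-cluster label), `centroids` (matrix, one medoid
#'   series per row), `dates` (day-of-year axis of the centroids), `cost`,
#'   `step_pattern`, `window`, `pad_km`.
#' @seealso [predict.contingent_cluster()] to classify later-year tracks onto
#'   the fitted centroids.
#' @examples
#' x <- rbind(a = c(35, 60, 90, 60, 35), b = c(35, 62, 95, 62, 35),
#'            c = c(35, 120, 180, 120, 35), d = c(35, 118, 175, 119, 35))
#' fit <- contingent_cluster(x, k = 2)
#' fit$contingent
#' @export
contingent_cluster <- function(x, k = 2,
                               step_pattern = c("symmetric2", "symmetric1"),
                               window = NULL, diss = NULL) {
  step_pattern <- match.arg(step_pattern)
  X <- unclass(as.matrix(x))
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  if (is.null(diss))
    diss <- dtw_dissimilarity(X, step_pattern = step_pattern, window = window)
  fit <- pam_cluster(diss, k)
  centroids <- X[fit$medoids, , drop = FALSE]
  labels <- if (k == 2) {
    pk <- apply(centroids, 1L, max)
    ifelse(rank(-pk, ties.method = "first") == 1L, "upper", "lower")
  } else if (k == 1) "all" else sprintf("C%d", seq_len(k))
  dates <- attr(x, "dates")
  doy <- if (!is.null(dates)) as.integer(format(dates, "%j")) else seq_len(ncol(X))
  structure(list(
    k = k, diss = diss, medoids = fit$medoids,
    assignment = setNames(fit$assignment, rownames(X)),
    contingent = setNames(labels[fit$assignment], rownames(X)),
    labels = labels, centroids = centroids, dates = doy,
    cost = fit$cost, step_pattern = step_pattern, window = window,
    pad_km = if (is.null(attr(x, "pad_km"))) min(X) else attr(x, "pad_km")),
    class = "contingent_cluster")
}

#' @export
print.contingent_cluster <- function(x, ...) {
  cat(sprintf("DTW k-medoids contingent model (k = %d, %s, L1)\n",
              x$k, x$step_pattern))
  cat(sprintf("  %d series, total within-cluster cost %.4g\n",
              length(x$assignment), x$cost))
  for (j in seq_len(x$k))
    cat(sprintf("  cluster %d ('%s'): %d series, medoid '%s', peak km %.1f\n",
                j, x$labels[j], sum(x$assignment == j),
                names(x$assignment)[x$medoids[j]], max(x$centroids[j, ])))
  invisible(x)
}

#' @export
summary.contingent_cluster <- function(object, ...) {
  print(object)
  cat("Cluster sizes:\n")
  print(table(object$contingent))
  invisible(object)
}

#' @export
plot.contingent_cluster <- function(x, ...) {
  matplot(x$dates, t(x$centroids), type = "l", lty = 1, lwd = 2,
          xlab = "day of year", ylab = "river km",
          main = "Contingent centroids (medoid phenologies)", ...)
  legend("topright", legend = x$labels, col = seq_len(x$k), lty = 1, lwd = 2)
  invisible(x)
}

#' Classify new phenology series onto fitted centroids
#'
#' Later-year tracks are labelled by their nearest centroid under the model's
#' DTW settings. New series and centroids are re-padded onto the union of
#' their day-of-year spans with the model's padding constant, so runs from a
#' different calendar year are compared on a seasonal axis. A series exactly
#' equidistant from two centroids takes the lower-index centroid and is
#' flagged.
#'
#' @param object A fitted [contingent_cluster()] model.
#' @param newdata Named list of `run_segment`s, or a `phenology_matrix`.
#' @param ... Unused.
#' @return Data frame with `tag_id`, `cluster`, `contingent`, `distance`,
#'   `tie`.
#' @export
predict.contingent_cluster <- function(object, newdata, ...) {
  if (object$k < 1 || is.null(object$centroids) || !nrow(object$centroids))
    stop("model has no centroids", call. = FALSE)
  new_series <- as_doy_series(newdata)
  doy_all <- c(object$dates,
               unlist(lapply(new_series, function(s) s$doy), use.names = FALSE))
  axis <- seq(min(doy_all), max(doy_all))
  pad <- object$pad_km
  place <- function(doy, km) {
    v <- rep(pad, length(axis))
    v[match(doy, axis)] <- km
    v
  }
  C <- t(vapply(seq_len(nrow(object$centroids)), function(j)
    place(object$dates, object$centroids[j, ]), numeric(length(axis))))
  out <- lapply(names(new_series), function(tag) {
    s <- place(new_series[[tag]]$doy, new_series[[tag]]$km)
    dd <- vapply(seq_len(nrow(C)), function(j)
      dtw_distance(s, C[j, ], step_pattern = object$step_pattern,
                   window = object$window)$distance, numeric(1))
    tie <- sum(dd == min(dd)) > 1L
    data.frame(tag_id = tag, cluster = which.min(dd),
               contingent = object$labels[which.min(dd)],
               distance = min(dd), tie = tie, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(res$tie))
    warning(sum(res$tie), " series equidistant from two centroids; ",
            "assigned to the lower-index centroid", call. = FALSE)
  rownames(res) <- NULL
  res
}

# normalize newdata to a named list of (doy, km) series
as_doy_series <- function(newdata) {
  if (inherits(newdata, "phenology_matrix") ||
      (is.matrix(newdata) && !is.null(attr(newdata, "dates")))) {
    doy <- as.integer(format(attr(newdata, "dates"), "%j"))
    X <- unclass(newdata)
    setNames(lapply(seq_len(nrow(X)), function(i)
      list(doy = doy, km = X[i, ])), rownames(X))
  } else if (is.list(newdata) && length(newdata) &&
             all(vapply(newdata, inherits, logical(1), "run_segment"))) {
    if (is.null(names(newdata)))
      names(newdata) <- sprintf("S%03d", seq_along(newdata))
    lapply(newdata, function(seg)
      list(doy = as.integer(format(seg$series$date, "%j")),
           km = seg$series$river_km))
  } else {
    stop("newdata must be a phenology_matrix or a list of run_segments",
         call. = FALSE)
  }
}

#' Cross-classification of contingent labels between two years
#'
#' Tabulates, over the fish labelled in both years, year-1 versus year-2
#' contingent labels; reports the concordance fraction and a Pearson
#' chi-square test of independence (Yates continuity correction by default
#' for 2x2 tables).
#'
#' @param labels_y1,labels_y2 Named character vectors (names = tag ids).
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return Object of class `cross_classification`: `table`, `n_shared`,
#'   `concordance`, `statistic`, `df`, `p_value`.
#' @export
cross_classify <- function(labels_y1, labels_y2, correct = TRUE) {
  shared <- intersect(names(labels_y1), names(labels_y2))
  if (!length(shared)) stop("no shared fish between years", call. = FALSE)
  lv <- sort(unique(c(labels_y1[shared], labels_y2[shared])))
  tab <- table(year1 = factor(labels_y1[shared], levels = lv),
               year2 = factor(labels_y2[shared], levels = lv))
  conc <- mean(labels_y1[shared] == labels_y2[shared])
  test <- tryCatch(
    suppressWarnings(chisq.test(tab, correct = correct)),
    error = function(e) NULL)
  structure(list(table = tab, n_shared = length(shared), concordance = conc,
                 statistic = if (is.null(test)) NA_real_ else unname(test$statistic),
                 df = if (is.null(test)) NA_integer_ else unname(test$parameter),
                 p_value = if (is.null(test)) NA_real_ else test$p.value),
            class = "cross_classification")
}

#' @export
print.cross_classification <- function(x, ...) {
  cat(sprintf("Cross-year classification of %d fish\n", x$n_shared))
  print(x$table)
  cat(sprintf("Concordance: %.0f%%", 100 * x$concordance))
  if (!is.na(x$statistic))
    cat(sprintf("  (chi-square = %.3g, df = %d, p = %.3g)",
                x$statistic, x$df, x$p_value))
  cat("\n")
  invisible(x)
}
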