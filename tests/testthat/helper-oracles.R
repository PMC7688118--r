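# Independent brute-force oracles and small fixture builders used across tests.

# DTW by exhaustive enumeration of every monotone warping path (DFS over
# steps (1,0), (0,1), (1,1)); independent of the package's dynamic program.
brute_dtw <- function(a, b, diag_weight = 2) {
  n <- length(a); m <- length(b)
  best <- Inf
  rec <- function(i, j, acc) {
    if (acc >= best) return()
    if (i == n && j == m) { best <<- acc; return() }
    if (i < n && j < m) rec(i + 1, j + 1, acc + diag_weight * abs(a[i + 1] - b[j + 1]))
    if (i < n) rec(i + 1, j, acc + abs(a[i + 1] - b[j]))
    if (j < m) rec(i, j + 1, acc + abs(a[i] - b[j + 1]))
  }
  rec(1, 1, abs(a[1] - b[1]))
  best
}

# k-medoids by exhaustive search over all medoid subsets of size k
brute_pam_cost <- function(d, k = 2) {
  n <- nrow(d)
  combs <- utils::combn(n, k)
  min(apply(combs, 2, function(med)
    sum(apply(d[, med, drop = FALSE], 1, min))))
}

random_diss <- function(n) {
  d <- matrix(runif(n * n, 0.1, 10), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# survival records with deaths at given times and censoring at `end`
make_records <- function(death_times, n_censored, end, group = "g") {
  data.frame(
    tag_id = sprintf("%s%03d", group, seq_len(length(death_times) + n_censored)),
    group = group,
    time_days = c(death_times, rep(end, n_censored)),
    event = rep(c(TRUE, FALSE), c(length(death_times), n_censored)),
    stringsAsFactors = FALSE)
}

# a small deterministic run segment on consecutive dates
make_segment <- function(start, kms, provenance = NULL) {
  dates <- as.Date(start) + seq_along(kms) - 1
  if (is.null(provenance)) provenance <- rep("observed", length(kms))
  structure(list(entry_date = dates[1], exit_date = dates[length(kms)],
                 series = data.frame(date = dates, river_km = kms,
                                     provenance = provenance,
                                     stringsAsFactors = FALSE)),
            class = "run_segment")
}

default_receivers_for_test <- function()
  runcontingent:::default_receivers(synthetic_config())

# adjusted Rand index between two label vectors (mclust if present)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  exp_ <- si * sj / ch2(sum(tab))
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
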