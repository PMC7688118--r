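#' Dynamic time warping distance between two series
#'
#' Computes the minimum cumulative alignment cost between two numeric series
#' under an L1 local cost `|a_i - b_j|`, with steps restricted to
#' (1,0), (0,1), (1,1). Under `"symmetric2"` (the default) a diagonal step
#' weighs the local cost twice, which removes the bias toward diagonal paths;
#' `"symmetric1"` weighs all steps once. Distances are unnormalized path
#' costs. The warp may optionally be constrained to a Sakoe-Chiba band.
#'
#' @param a,b Nonempty numeric vectors.
#' @param step_pattern `"symmetric2"` or `"symmetric1"`.
#' @param window Optional band half-width on `|i - j|`; must be at least
#'   `abs(length(a) - length(b))` for the end point to be reachable.
#' @return Object of class `dtw_warp`: list with `distance` (nonnegative) and
#'   `path` (two-column matrix of matched 1-based index pairs from `(1,1)` to
#'   `(n,m)`).
#' @examples
#' dtw_distance(c(0, 1), c(1, 0))$distance  # 2
#' @export
dtw_distance <- function(a, b, step_pattern = c("symmetric2", "symmetric1"),
                         window = NULL) {
  step_pattern <- match.arg(step_pattern)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("series must be nonempty", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("series must not contain NA", call. = FALSE)
  win <- if (is.null(window)) -1L else as.integer(window)
  if (win >= 0L && win < abs(length(a) - length(b)))
    stop("window smaller than the length difference: end point unreachable",
         call. = FALSE)
  r <- .dtw_core(a, b, if (step_pattern == "symmetric2") 2L else 1L, win, TRUE)
  structure(list(distance = r$distance, path = r$path,
                 step_pattern = step_pattern),
            class = "dtw_warp")
}

#' @export
print.dtw_warp <- function(x, ...) {
  cat(sprintf("DTW alignment (%s, L1): distance %.4g, path length %d\n",
              x$step_pattern, x$distance, nrow(x$path)))
  invisible(x)
}

#' Pairwise DTW dissimilarity matrix
#'
#' @param x Numeric matrix of equal-length series in rows (e.g. a
#'   [catenate_pad()] result) or a list of equal-length numeric vectors.
#' @inheritParams dtw_distance
#' @return Symmetric matrix with zero diagonal; row/col names carried over.
#' @export
dtw_dissimilarity <- function(x, step_pattern = c("symmetric2", "symmetric1"),
                              window = NULL) {
  step_pattern <- match.arg(step_pattern)
  if (is.list(x) && !is.data.frame(x)) {
    len <- lengths(x)
    if (length(unique(len)) != 1L)
      stop("series have unequal lengths; catenate/pad them first",
           call. = FALSE)
    x <- do.call(rbind, x)
  }
  X <- unclass(as.matrix(x))
  win <- if (is.null(window)) -1L else as.integer(window)
  D <- .dtw_pairwise(X, if (step_pattern == "symmetric2") 2L else 1L, win)
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}
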