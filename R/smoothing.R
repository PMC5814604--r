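#' Per-cluster mean diel curves
#'
#' Averages the feature rows of each cluster's members into one 1440-minute
#' curve. Raw-MET features (10,080 minutes) are first averaged over members,
#' then folded over the 7 day-blocks to a single minute-of-day curve, so both
#' feature kinds share the same daily axis. Normalized MVPA features are
#' averaged directly.
#'
#' @param features A `feature_matrix`.
#' @param labels Integer cluster labels (1..k) aligned with feature rows.
#' @return A k x 1440 matrix, row j = mean curve of cluster j.
#' @export
cluster_mean_curve <- function(features, labels) {
  x <- unclass_matrix(features)
  stopifnot(length(labels) == nrow(x))
  k <- max(labels)
  if (any(tabulate(labels, k) == 0L)) stop("empty cluster in labels")
  means <- rowsum(x, labels, reorder = TRUE) / tabulate(labels, k)
  if (ncol(means) == MINUTES_PER_WEEK) {
    # fold the week onto minute-of-day: average the 7 day-blocks
    means <- t(apply(means, 1L, function(row) {
      rowMeans(matrix(row, nrow = MINUTES_PER_DAY, ncol = DAYS_PER_WEEK))
    }))
  }
  stopifnot(ncol(means) == MINUTES_PER_DAY)
  rownames(means) <- seq_len(k)
  means
}

#' Loess smoothing of a diel curve
#'
#' Classical locally weighted regression: at each minute, a degree-1
#' polynomial is fitted over the nearest `span` fraction of points with
#' tricube weights and evaluated there. The day is treated as non-circular
#' (no wraparound at midnight) and no robustness iterations are applied.
#' Degree-1 loess reproduces constant and exactly linear curves.
#'
#' @param curve Finite numeric vector (one value per minute).
#' @param span Fraction of points in each local window, default 0.1.
#' @param degree Local polynomial degree; only 1 is supported.
#' @return Smoothed vector of the same length.
#' @export
loess_smooth <- function(curve, span = 0.1, degree = 1L) {
  stopifnot(is.numeric(curve), all(is.finite(curve)), degree == 1L,
            span > 0, span <= 1)
  n <- length(curve)
  if (ceiling(span * n) < 3L) {
    stop("span ", span, " yields a local window of fewer than 3 points")
  }
  t <- seq_len(n) - 1
  fit <- stats::loess(curve ~ t, span = span, degree = degree,
                      family = "gaussian", surface = "direct")
  as.numeric(stats::predict(fit, data.frame(t = t)))
}

#' Smoothed per-cluster diel curves
#'
#' Combines [cluster_mean_curve()] and [loess_smooth()] into the object the
#' figure plots and cluster naming work from.
#'
#' @inheritParams cluster_mean_curve
#' @param span Loess span, default 0.1.
#' @return An object of class `smoothed_curves`: `minute` (0..1439), `mean`
#'   and `smoothed` (k x 1440 matrices), `span`, `kind`.
#' @export
smoothed_curves <- function(features, labels, span = 0.1) {
  means <- cluster_mean_curve(features, labels)
  smoothed <- t(apply(means, 1L, loess_smooth, span = span))
  rownames(smoothed) <- rownames(means)
  structure(list(minute = 0:(MINUTES_PER_DAY - 1L), mean = means,
                 smoothed = smoothed, span = span,
                 kind = if (inherits(features, "feature_matrix"))
                   feature_kind(features) else NA_character_),
            class = "smoothed_curves")
}

#' @export
print.smoothed_curves <- function(x, ...) {
  cat(sprintf("<smoothed_curves> %d clusters x %d minutes, span=%.3g, kind=%s\n",
              nrow(x$smoothed), length(x$minute), x$span, x$kind))
  invisible(x)
}

#' Long-format data frame of smoothed curves
#'
#' @param curves A `smoothed_curves` object.
#' @return Data frame with columns `minute`, `cluster`, `raw_mean`,
#'   `smoothed`, suitable for CSV export or plotting.
#' @export
curves_table <- function(curves) {
  stopifnot(inherits(curves, "smoothed_curves"))
  k <- nrow(curves$smoothed)
  data.frame(
    minute = rep(curves$minute, times = k),
    cluster = rep(seq_len(k), each = length(curves$minute)),
    raw_mean = as.numeric(t(curves$mean)),
    smoothed = as.numeric(t(curves$smoothed))
  )
}
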