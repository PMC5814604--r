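#' Lloyd k-means with random restarts
#'
#' Plain Lloyd iteration on squared Euclidean distance: each restart draws k
#' distinct data rows uniformly as initial centroids, then alternates
#' assign-to-nearest and recompute-means until the assignment reaches a fixed
#' point, the relative WSS change drops below `tol`, or `max_iter` is hit.
#' An emptied cluster is repaired by seizing the point currently farthest
#' from its own centroid. The reported solution is the restart with minimal
#' within-group sum of squares (ties broken by lowest restart index). No
#' feature standardization is applied: distance acts on the matrix as-is.
#'
#' @param features A `feature_matrix` or plain numeric matrix (no missing
#'   entries).
#' @param k Number of clusters, `1 <= k <= nrow(features)`.
#' @param restarts Number of random initializations, default 25.
#' @param seed Optional RNG seed; all restarts flow from this one stream.
#' @param max_iter Iteration cap per restart.
#' @param tol Relative WSS-change convergence threshold.
#' @param init `"sample"` (uniform k distinct rows, the default) or
#'   `"kmeans++"` (distance-proportional seeding).
#' @param extra_init Optional list of k x p centroid matrices appended as
#'   additional deterministic restarts (used by [elbow_scan()] warm starts).
#' @return An object of class `lloyd_kmeans` with fields `labels` (1..k,
#'   named by row), `centroids`, `wss`, `tss`, `variance_explained`,
#'   `restarts`, `seed`, `per_restart_wss`, `iter_wss` (WSS trace of the
#'   winning restart), `best_restart`.
#' @export
lloyd_kmeans <- function(features, k, restarts = 25L, seed = NULL,
                         max_iter = 100L, tol = 1e-10,
                         init = c("sample", "kmeans++"), extra_init = NULL) {
  init <- match.arg(init)
  x <- unclass_matrix(features)
  n <- nrow(x)
  if (k <= 0L) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the number of rows (", n, ")")
  if (anyNA(x)) stop("feature matrix contains missing entries")
  if (!is.null(seed)) set.seed(seed)

  xsq <- rowSums(x^2)
  grand <- colMeans(x)
  tss <- sum(xsq) - n * sum(grand^2)

  inits <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    idx <- if (init == "sample") sample.int(n, k) else kmeanspp_init(x, k, xsq)
    inits[[r]] <- x[idx, , drop = FALSE]
  }
  if (!is.null(extra_init)) inits <- c(inits, extra_init)

  best <- NULL
  per_restart_wss <- numeric(length(inits))
  for (r in seq_along(inits)) {
    fit <- run_lloyd(x, xsq, inits[[r]], max_iter, tol)
    per_restart_wss[r] <- fit$wss
    if (is.null(best) || fit$wss < best$wss) {
      best <- fit
      best$restart <- r
    }
  }

  labels <- best$labels
  names(labels) <- rownames(x)
  structure(list(labels = labels, centroids = best$centroids,
                 wss = best$wss, tss = tss,
                 variance_explained = if (tss > 0) 1 - best$wss / tss else 1,
                 restarts = restarts, seed = seed,
                 per_restart_wss = per_restart_wss,
                 iter_wss = best$iter_wss, best_restart = best$restart,
                 k = k),
            class = "lloyd_kmeans")
}

unclass_matrix <- function(features) {
  x <- features
  if (inherits(x, "feature_matrix")) {
    attr(x, "kind") <- NULL
    class(x) <- "matrix"
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

kmeanspp_init <- function(x, k, xsq) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- pmax(xsq + xsq[idx[1]] - 2 * drop(x %*% x[idx[1], ]), 0)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx[j] <- sample(setdiff(seq_len(n), idx[seq_len(j - 1L)]), 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, pmax(xsq + xsq[idx[j]] - 2 * drop(x %*% x[idx[j], ]), 0))
    }
  }
  idx
}

run_lloyd <- function(x, xsq, centroids, max_iter, tol) {
  n <- nrow(x)
  k <- nrow(centroids)
  labels <- integer(n)
  iter_wss <- numeric(0)
  wss <- Inf
  for (it in seq_len(max_iter)) {
    csq <- rowSums(centroids^2)
    # argmin_j ||x - c_j||^2 = argmax_j (2 x.c_j - ||c_j||^2); xsq is constant per row
    score <- 2 * (x %*% t(centroids)) - rep(csq, each = n)
    new_labels <- max.col(score, ties.method = "first")

    # repair empty clusters: seize the point farthest from its own centroid
    for (j in which(tabulate(new_labels, k) == 0L)) {
      d2 <- xsq - score[cbind(seq_len(n), new_labels)]
      movable <- tabulate(new_labels, k)[new_labels] > 1L
      cand <- which(movable)
      new_labels[cand[which.max(d2[cand])]] <- j
    }

    counts <- tabulate(new_labels, k)
    centroids <- rowsum(x, new_labels, reorder = TRUE) / counts
    csq <- rowSums(centroids^2)
    new_wss <- sum(xsq) - sum(counts * csq)
    iter_wss <- c(iter_wss, new_wss)

    converged <- identical(new_labels, labels) ||
      (is.finite(wss) && wss > 0 && abs(wss - new_wss) / wss < tol)
    labels <- new_labels
    wss <- new_wss
    if (converged) break
  }
  list(labels = labels, centroids = centroids, wss = wss, iter_wss = iter_wss)
}

#' @export
print.lloyd_kmeans <- function(x, ...) {
  cat(sprintf("<lloyd_kmeans> k=%d, n=%d, WSS=%.4g, variance explained=%.1f%% (%d restarts)\n",
              x$k, length(x$labels), x$wss, 100 * x$variance_explained, x$restarts))
  invisible(x)
}

#' Elbow rule on a WSS-by-k sequence
#'
#' Chooses the smallest k at which adding one more cluster no longer reduces
#' the within-group sum of squares by at least `threshold` (relative to the
#' current WSS); returns `k_max` when every step is still a large reduction.
#'
#' @param wss_by_k WSS values for k = 1..k_max.
#' @param threshold Relative-reduction cutoff, default 0.10.
#' @return The chosen k.
#' @export
choose_elbow_k <- function(wss_by_k, threshold = 0.10) {
  stopifnot(length(wss_by_k) >= 2L, all(is.finite(wss_by_k)))
  k_max <- length(wss_by_k)
  for (k in seq_len(k_max - 1L)) {
    if (wss_by_k[k] <= 0) return(k)
    if ((wss_by_k[k] - wss_by_k[k + 1L]) / wss_by_k[k] < threshold) return(k)
  }
  k_max
}

#' Scan k = 1..k_max and select the elbow
#'
#' Runs [lloyd_kmeans()] for each k with the same restart budget, recording
#' the best WSS per k, and applies the elbow rule. Each k > 1 additionally
#' gets one deterministic warm-start restart built from the best (k-1)
#' solution (its centroids plus the point farthest from its assigned
#' centroid), which guarantees the WSS sequence is non-increasing in k.
#'
#' @inheritParams lloyd_kmeans
#' @param k_max Largest k scanned (>= 2).
#' @param threshold Elbow relative-reduction cutoff, default 0.10.
#' @return An object of class `elbow_scan`: `k_values`, `wss_by_k`,
#'   `chosen_k`, `threshold`, `fits` (the per-k `lloyd_kmeans` fits).
#' @export
elbow_scan <- function(features, k_max, restarts = 25L, seed = NULL,
                       threshold = 0.10, max_iter = 100L, tol = 1e-10) {
  stopifnot(k_max >= 2L)
  x <- unclass_matrix(features)
  fits <- vector("list", k_max)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, k_max)
  for (k in seq_len(k_max)) {
    warm <- if (k > 1L) list(split_centroid_init(x, fits[[k - 1L]])) else NULL
    fits[[k]] <- lloyd_kmeans(features, k, restarts = restarts, seed = seeds[k],
                              max_iter = max_iter, tol = tol, extra_init = warm)
  }
  wss_by_k <- vapply(fits, function(f) f$wss, numeric(1))
  structure(list(k_values = seq_len(k_max), wss_by_k = wss_by_k,
                 chosen_k = choose_elbow_k(wss_by_k, threshold),
                 threshold = threshold, fits = fits),
            class = "elbow_scan")
}

# previous best centroids + the worst-fit data point as the extra centroid
split_centroid_init <- function(x, fit) {
  cent <- fit$centroids
  d2 <- rowSums((x - cent[fit$labels, , drop = FALSE])^2)
  rbind(cent, x[which.max(d2), ])
}

#' @export
print.elbow_scan <- function(x, ...) {
  cat("<elbow_scan> chosen k =", x$chosen_k, "\n")
  print(data.frame(k = x$k_values, wss = x$wss_by_k))
  invisible(x)
}

#' Name clusters from their smoothed diel curves
#'
#' Assigns interpretable names by inspecting each cluster's loess-smoothed
#' mean curve. For raw-MET curves: the cluster with the lowest time-averaged
#' level is `"unengaged"`; the rest are `"morning"` or `"afternoon"` by
#' whether the curve peaks before or after noon (minute 720). For normalized
#' MVPA curves: a curve with two well-separated local maxima (>= 6 h apart)
#' is `"morning_and_evening_peak"`; otherwise the name follows the peak
#' minute — `"morning_peak"` (< 600), `"noon_peak"` (600..839) or
#' `"evening_peak"` (>= 840). Duplicate names get a `_1`, `_2`, ... suffix in
#' cluster-index order, so ties break deterministically by cluster index.
#'
#' @param result A `lloyd_kmeans` fit.
#' @param curves A `smoothed_curves` object (see [smoothed_curves()]) for the
#'   same fit.
#' @param kind `"raw"` or `"normalized_mvpa"`.
#' @return Named character vector: element j is the name of cluster j.
#' @export
name_clusters <- function(result, curves, kind = c("raw", "normalized_mvpa")) {
  kind <- match.arg(kind)
  stopifnot(inherits(result, "lloyd_kmeans"), inherits(curves, "smoothed_curves"))
  sm <- curves$smoothed # k x 1440
  stopifnot(nrow(sm) == result$k)
  k <- result$k
  names_out <- character(k)
  if (kind == "raw") {
    lowest <- which.min(rowMeans(sm))
    for (j in seq_len(k)) {
      if (j == lowest) {
        names_out[j] <- "unengaged"
      } else {
        peak <- which.max(sm[j, ]) - 1L
        names_out[j] <- if (peak < 720L) "morning" else "afternoon"
      }
    }
  } else {
    for (j in seq_len(k)) {
      peaks <- curve_peaks(sm[j, ])
      if (length(peaks) >= 2L && max(peaks) - min(peaks) >= 360L) {
        names_out[j] <- "morning_and_evening_peak"
      } else {
        peak <- which.max(sm[j, ]) - 1L
        names_out[j] <- if (peak < 600L) "morning_peak"
                        else if (peak < 840L) "noon_peak"
                        else "evening_peak"
      }
    }
  }
  out <- make.unique(names_out, sep = "_")
  names(out) <- seq_len(k)
  out
}

# local maxima of a smoothed curve: highest point within a +/- 60-minute
# window and at least half the global peak height above the curve minimum
curve_peaks <- function(y, window = 60L, height_frac = 0.5) {
  n <- length(y)
  rng <- max(y) - min(y)
  if (rng <= 0) return(integer(0))
  peaks <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window); hi <- min(n, i + window)
    if (y[i] >= max(y[lo:hi]) && (y[i] - min(y)) >= height_frac * rng) {
      # keep only the first index of a flat plateau
      if (length(peaks) == 0L || i - peaks[length(peaks)] > window) {
        peaks <- c(peaks, i)
      }
    }
  }
  peaks - 1L
}
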