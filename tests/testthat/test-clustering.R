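test_that("k-means solves trivially separated data and the k=1 closed form", {
  x <- matrix(c(0, 0, 10, 10), ncol = 1)
  rownames(x) <- paste0("p", 1:4)
  fit <- lloyd_kmeans(x, 2, restarts = 5, seed = 1)
  expect_equal(sort(as.numeric(fit$centroids)), c(0, 10))
  expect_equal(fit$wss, 0)
  expect_equal(fit$variance_explained, 1)

  set.seed(2)
  y <- matrix(rnorm(40), ncol = 2, dimnames = list(paste0("p", 1:20), NULL))
  fit1 <- lloyd_kmeans(y, 1, restarts = 3, seed = 1)
  expect_equal(as.numeric(fit1$centroids), colMeans(y), tolerance = 1e-12)
  expect_equal(fit1$wss, fit1$tss, tolerance = 1e-12)
  expect_equal(fit1$variance_explained, 0)

  expect_error(lloyd_kmeans(y, 0), "k must be")
  expect_error(lloyd_kmeans(y, 21), "exceeds")
})

test_that("centroids equal their cluster means and clusters are nonempty", {
  set.seed(3)
  x <- matrix(rnorm(60 * 4), ncol = 4, dimnames = list(sprintf("p%02d", 1:60), NULL))
  fit <- lloyd_kmeans(x, 4, restarts = 10, seed = 3)
  expect_true(all(tabulate(fit$labels, 4) > 0))
  for (j in 1:4) {
    expect_equal(as.numeric(fit$centroids[j, ]),
                 colMeans(x[fit$labels == j, , drop = FALSE]), tolerance = 1e-9)
  }
  expect_equal(fit$wss, min(fit$per_restart_wss))
  expect_true(all(fit$per_restart_wss >= fit$wss))
  expect_gte(fit$variance_explained, 0)
  expect_lte(fit$variance_explained, 1)
})

test_that("WSS is non-increasing across Lloyd iterations", {
  set.seed(4)
  for (i in 1:10) {
    x <- matrix(rnorm(40 * 3), ncol = 3,
                dimnames = list(sprintf("p%02d", 1:40), NULL))
    fit <- lloyd_kmeans(x, 3, restarts = 5, seed = i)
    expect_true(all(diff(fit$iter_wss) <= 1e-9))
  }
})

test_that("25 restarts reach the exhaustive-partition optimum on small data", {
  set.seed(5)
  hits <- 0
  for (i in 1:20) {
    n <- sample(5:8, 1)
    x <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(paste0("p", 1:n), NULL))
    fit <- lloyd_kmeans(x, 2, restarts = 25, seed = i)
    if (fit$wss <= oracle_best_wss_k2(x) + 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("best-of-restarts agrees with an independent Lloyd implementation", {
  # well-separated planted clusters: both solvers must find the optimum
  set.seed(6)
  x <- rbind(matrix(rnorm(30, 0, .2), ncol = 2),
             matrix(rnorm(30, 5, .2), ncol = 2),
             matrix(rnorm(30, c(0, 10), .2), ncol = 2))
  rownames(x) <- sprintf("p%02d", 1:45)
  ours <- lloyd_kmeans(x, 3, restarts = 25, seed = 6)
  ref <- stats::kmeans(x, 3, nstart = 25, algorithm = "Lloyd")
  expect_equal(ours$wss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("relabeling clusters leaves WSS and names unchanged", {
  set.seed(7)
  x <- matrix(rnorm(30 * 2), ncol = 2, dimnames = list(paste0("p", 1:30), NULL))
  fit <- lloyd_kmeans(x, 3, restarts = 10, seed = 7)
  perm <- c(2L, 3L, 1L)
  relabeled <- perm[fit$labels]
  wss_perm <- sum(vapply(1:3, function(j) {
    xs <- x[relabeled == j, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
  expect_equal(wss_perm, fit$wss, tolerance = 1e-9)
})

test_that("elbow rule picks the first sub-threshold reduction", {
  expect_equal(choose_elbow_k(c(100, 20, 19, 18)), 2L)
  expect_equal(choose_elbow_k(100 * 0.5^(0:4)), 5L)  # every step is 50%
  expect_equal(choose_elbow_k(c(100, 95, 90)), 1L)
  # a reduction of exactly the threshold still counts as significant
  expect_equal(choose_elbow_k(c(100, 50, 48, 10), threshold = 0.5), 2L)
})

test_that("elbow scan WSS is non-increasing in k and finds planted structure", {
  # three well-separated centers embedded in 100-dimensional noise: once the
  # true clusters are recovered, further splits only chase isotropic noise
  # and the relative WSS reduction collapses below the 10% threshold
  set.seed(8)
  p <- 100L
  centers <- matrix(0, 3, p)
  centers[1, 1] <- 8; centers[2, 2] <- 8; centers[3, 3] <- 8
  x <- centers[rep(1:3, each = 20), ] + matrix(rnorm(60 * p), 60, p)
  rownames(x) <- sprintf("p%02d", seq_len(nrow(x)))
  scan <- elbow_scan(x, k_max = 6, restarts = 25, seed = 8)
  expect_true(all(diff(scan$wss_by_k) <= 1e-9 * scan$fits[[1]]$tss))
  expect_equal(scan$chosen_k, 3L)
})

test_that("cluster naming follows curve shape rules", {
  k3 <- structure(list(k = 3L), class = "lloyd_kmeans")
  minute <- 0:1439
  bump <- function(center, height, base = 1) {
    base + height * exp(-(minute - center)^2 / (2 * 40^2))
  }
  raw_curves <- structure(list(
    minute = minute,
    smoothed = rbind(bump(540, 2), bump(900, 2), rep(1.0, 1440)),
    mean = NULL, span = 0.1, kind = "raw"), class = "smoothed_curves")
  nm <- name_clusters(k3, raw_curves, "raw")
  expect_equal(unname(nm), c("morning", "afternoon", "unengaged"))

  norm_curves <- structure(list(
    minute = minute,
    smoothed = rbind(bump(450, 0.05, 0) + bump(1050, 0.05, 0),  # 07:30 & 17:30
                     bump(720, 0.05, 0),
                     bump(1080, 0.05, 0)),
    mean = NULL, span = 0.1, kind = "normalized_mvpa"), class = "smoothed_curves")
  nm2 <- name_clusters(k3, norm_curves, "normalized_mvpa")
  expect_equal(unname(nm2),
               c("morning_and_evening_peak", "noon_peak", "evening_peak"))
})
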