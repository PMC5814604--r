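test_that("raw feature matrix imputes, orders rows by id, and keeps dimensions", {
  daily <- rep(NA_real_, MPD)
  daily[601] <- 5.0
  sparse <- make_trace("b_sparse", daily)
  # raw construction requires a validity-filtered cohort
  expect_error(raw_feature_matrix(cohort_dataset(list(sparse))), "8 h/day")

  cohort <- make_small_cohort(2L)
  fm <- raw_feature_matrix(cohort)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm), c(2L, 10080L))
  expect_equal(rownames(fm), c("p01", "p02"))
  expect_true(all(fm == 1.2))

  # one observed minute at 5 METs, the rest imputed to 1
  one_min <- rep(NA_real_, MPD); one_min[1:480] <- 1; one_min[200] <- 5
  tr <- make_trace("z1", one_min)
  fm2 <- raw_feature_matrix(cohort_dataset(list(tr)))
  expect_equal(sum(fm2 == 5), 7L)
  expect_true(all(fm2 %in% c(1, 5)))
})

test_that("MVPA binarization thresholds at 3 METs inclusive, missing maps to 0", {
  daily <- rep(1, MPD)
  daily[c(10, 20, 30)] <- c(3.0, 2.999, 6.5)
  daily[40] <- NA_real_
  bits <- binarize_mvpa(make_trace("p1", daily))
  expect_equal(bits[c(10, 20, 30, 40)], c(1L, 0L, 1L, 0L))
  expect_true(all(bits %in% 0:1))
  # missing -> 0 coincides with impute-1-then-threshold
  imp_bits <- binarize_mvpa(impute_missing(make_trace("p1", daily)))
  expect_identical(bits, imp_bits)
})

test_that("daily average profile counts active days out of 7", {
  bits <- rep(0L, MPW)
  bits[600 + 1 + (0:6) * MPD] <- 1L            # minute 600 active all 7 days
  bits[700 + 1 + (0:2) * MPD] <- 1L            # minute 700 active on 3 days
  prof <- daily_average_profile(bits)
  expect_length(prof, 1440L)
  expect_equal(prof[601], 1.0)
  expect_equal(prof[701], 3 / 7)
  expect_true(all(prof %in% ((0:7) / 7)))
  expect_equal(daily_average_profile(rep(0L, MPW)), rep(0, 1440L))
})

test_that("unit normalization returns exact unit vectors and flags zero profiles", {
  v <- rep(0, 1440); v[c(5, 6)] <- c(3 / 7, 4 / 7)
  u <- unit_normalize(v)
  expect_equal(u[c(5, 6)], c(0.6, 0.8))
  expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-12)
  expect_equal(unit_normalize(u), u)  # idempotent on unit vectors
  z <- unit_normalize(rep(0, 1440))
  expect_true(is_degenerate(z))
  expect_false(is_degenerate(u))
})

test_that("unit norm holds to 1e-12 across a 1000-profile fuzz suite", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    k <- sample(1:200, 1)
    prof <- rep(0, 1440)
    prof[sample(1440, k)] <- sample(1:7, k, replace = TRUE) / 7
    nrm <- sqrt(sum(unit_normalize(prof)^2))
    worst <- max(worst, abs(nrm - 1))
  }
  expect_lt(worst, 1e-12)
})

test_that("normalized feature pipeline handles degenerate participants per policy", {
  active_daily <- rep(1, MPD); active_daily[700:720] <- 4
  active2 <- rep(1, MPD); active2[300:320] <- 4
  flat <- rep(1, MPD)
  cohort <- cohort_dataset(list(make_trace("a", active_daily),
                                make_trace("b", active2),
                                make_trace("c", flat)))
  res <- normalized_feature_matrix(cohort)   # default: exclude
  expect_equal(dim(res$features), c(2L, 1440L))
  expect_equal(res$degenerate_ids, "c")
  expect_equal(unname(apply(res$features, 1, function(r) sqrt(sum(r^2)))),
               c(1, 1), tolerance = 1e-12)

  res2 <- normalized_feature_matrix(cohort, "keep_zero")
  expect_equal(dim(res2$features), c(3L, 1440L))
  expect_true(all(res2$features["c", ] == 0))

  all_flat <- cohort_dataset(list(make_trace("a", flat), make_trace("b", flat)))
  expect_error(normalized_feature_matrix(all_flat), "zero MVPA")
})

test_that("normalization chain is invariant to uniform activity scaling", {
  # same relative diel profile, active on 2 vs 6 days: identical direction
  base_minutes <- c(400:420, 800:815)
  week <- function(days_active) {
    m <- rep(1, MPW)
    for (d in seq_len(days_active)) m[(d - 1) * MPD + base_minutes] <- 4
    participant_trace("x", m)
  }
  u2 <- unit_normalize(daily_average_profile(binarize_mvpa(week(2))))
  u6 <- unit_normalize(daily_average_profile(binarize_mvpa(week(6))))
  # brute-force recomputation oracle: direction = indicator of active minutes
  ind <- rep(0, 1440); ind[base_minutes] <- 1
  oracle <- ind / sqrt(sum(ind))
  expect_equal(as.numeric(u2), oracle, tolerance = 1e-12)
  expect_equal(as.numeric(u6), oracle, tolerance = 1e-12)
})
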