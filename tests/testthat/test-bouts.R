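run_of <- function(...) {
  # build a day prefix from alternating (value, length) pairs
  spec <- list(...)
  bits <- integer(0)
  for (i in seq(1, length(spec), by = 2)) {
    bits <- c(bits, rep(spec[[i]], spec[[i + 1]]))
  }
  day1_week(bits)
}

test_that("1-minute criterion is the plain count of MVPA minutes", {
  expect_equal(mvpa_minutes_1min(rep(0L, MPW)), 0)
  expect_equal(mvpa_minutes_1min(rep(1L, MPW)), 10080)
  set.seed(1)
  bits <- rep(0L, MPW); bits[sample(MPW, 30)] <- 1L
  expect_equal(mvpa_minutes_1min(bits), 30)
})

test_that("5-minute criterion counts minutes in runs of >= 5", {
  expect_equal(mvpa_minutes_5min(run_of(1L, 4)), 0)
  expect_equal(mvpa_minutes_5min(run_of(1L, 7)), 7)
  expect_equal(mvpa_minutes_5min(run_of(1L, 6, 0L, 1, 1L, 3)), 6)
  expect_equal(mvpa_minutes_5min(run_of(1L, 6, 0L, 1, 1L, 3)),
               oracle_run_minutes(c(rep(1L, 6), 0L, rep(1L, 3))))
})

test_that("10-minute criterion bridges short gaps and requires span >= 10", {
  expect_equal(mvpa_minutes_10min(run_of(1L, 12)), 12)
  expect_equal(mvpa_minutes_10min(run_of(1L, 6, 0L, 2, 1L, 6)), 12)   # span 14
  expect_equal(mvpa_minutes_10min(run_of(1L, 4, 0L, 3, 1L, 7)), 0)    # gap 3
  # spec'd patterns agree with the exhaustive pair oracle
  for (pat in list(c(rep(1L, 6), 0L, 0L, rep(1L, 6)),
                   c(rep(1L, 4), 0L, 0L, 0L, rep(1L, 7)),
                   rep(1L, 12))) {
    expect_equal(mvpa_minutes_10min(day1_week(pat)),
                 oracle_bout_minutes_pairs(pat))
  }
})

test_that("bouts and runs never span the midnight day boundary", {
  bits <- rep(0L, MPW)
  bits[(MPD - 5L):(MPD + 6L)] <- 1L    # 6 ones end of day 1, 6 start of day 2
  expect_equal(mvpa_minutes_5min(bits), 12)        # two runs of 6, each >= 5
  expect_equal(mvpa_minutes_10min(bits), 0)        # neither day reaches span 10
  bits2 <- rep(0L, MPW)
  bits2[(MPD - 11L):(MPD + 12L)] <- 1L             # 12 ones on each side
  expect_equal(mvpa_minutes_10min(bits2), 24)
})

test_that("bout implementations match oracles on random strings and edge lengths", {
  # exhaustive over all strings of length 10 placed on day 1
  B <- all_bitstrings(10L)
  impl5 <- apply(B, 1L, function(b) mvpa_minutes_5min(day1_week(b)))
  impl10 <- apply(B, 1L, function(b) mvpa_minutes_10min(day1_week(b)))
  expect_equal(impl5, oracle_run_minutes_mat(B))
  expect_equal(impl10, oracle_bout_minutes_mat_pairs(B))

  # random day-length strings at mixed densities
  set.seed(7)
  for (p in c(0.05, 0.3, 0.7)) {
    bits <- rbinom(MPD, 1L, p)
    expect_equal(mvpa_minutes_5min(day1_week(bits)),
                 oracle_run_minutes(bits))
    expect_equal(mvpa_minutes_10min(day1_week(bits)),
                 oracle_bout_minutes_mat_windows(matrix(bits, 1L)))
  }
})

test_that("increasing the interruption allowance never decreases bout minutes", {
  set.seed(11)
  for (i in 1:20) {
    bits <- day1_week(rbinom(MPD, 1L, runif(1, 0.05, 0.5)))
    vals <- vapply(0:4, function(g) mvpa_minutes_10min(bits, max_gap_run = g),
                   numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("1-minute total equals 7 x the daily-average profile sum", {
  set.seed(3)
  bits <- rbinom(MPW, 1L, 0.1)
  expect_equal(mvpa_minutes_1min(bits), 7 * sum(daily_average_profile(bits)))
})

test_that("mean daily steps divides the weekly total by 7", {
  steps_daily <- rep(0, MPD); steps_daily[1:70] <- 100
  tr <- make_trace("p1", rep(1, MPD), steps_daily = steps_daily)
  expect_equal(mean_daily_steps(tr), 7000)
  # steps on one day only: still divide by 7
  m <- rep(1, MPW); s <- rep(0, MPW); s[1:70] <- 100
  expect_equal(mean_daily_steps(participant_trace("p1", m, s)), 1000)
  expect_true(is.na(mean_daily_steps(make_trace("p1"))))
})

test_that("bout summary table is ordered, bounded, and internally consistent", {
  g <- generate_cohort(default_trial_config(seed = 5))
  small <- cohort_subset_ids(g$cohort, sort(names(g$cohort$traces))[1:10])
  bs <- bout_summary(small)
  expect_equal(bs$participant_id, sort(bs$participant_id))
  expect_true(all(bs$weekly_mvpa_1min >= bs$weekly_mvpa_5min))
  expect_true(all(bs$weekly_mvpa_1min <= 10080))
  expect_true(all(bs$weekly_mvpa_1min >= 0))
})
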