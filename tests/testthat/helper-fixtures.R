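# fixtures built in code: tiny traces, cohorts and CSVs

MPD <- 1440L
MPW <- 10080L

# trace from a 1440-length daily pattern repeated over 7 days
make_trace <- function(id = "p1", daily = rep(1, MPD), steps_daily = NULL) {
  participant_trace(id, rep(daily, 7L),
                    if (is.null(steps_daily)) NULL else rep(steps_daily, 7L))
}

# trace worn only in [wake, bed), METs = `level` while worn
make_wear_trace <- function(id = "p1", wake = 360L, bed = 1320L, level = 1.2) {
  daily <- rep(NA_real_, MPD)
  daily[(wake + 1L):bed] <- level
  make_trace(id, daily)
}

# small fully-observed cohort with n participants and an optional covariate df
make_small_cohort <- function(n = 3L, level = 1.2, covariates = NULL) {
  traces <- lapply(seq_len(n), function(i) make_trace(sprintf("p%02d", i),
                                                      rep(level, MPD)))
  cohort_dataset(traces, covariates)
}

# write a long CSV for given (id, day, minute, mets[, steps]) data frame
write_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# --- independent bout oracles -----------------------------------------------

# 5-minute criterion: a minute counts iff it is covered by a window of
# `min_run` consecutive ones (direct window check, no run-length encoding)
oracle_run_minutes <- function(bits, min_run = 5L) {
  n <- length(bits)
  if (n < min_run) return(0)
  covered <- logical(n)
  for (a in seq_len(n - min_run + 1L)) {
    if (all(bits[a:(a + min_run - 1L)] == 1L)) covered[a:(a + min_run - 1L)] <- TRUE
  }
  sum(bits == 1L & covered)
}

# 10-minute criterion, exhaustive pair enumeration: a minute counts iff some
# segment [a,b] contains it with one-bits at both ends, span >= min_span, and
# no interior gap of more than max_gap zeros
oracle_bout_minutes_pairs <- function(bits, max_gap = 2L, min_span = 10L) {
  n <- length(bits)
  ones <- which(bits == 1L)
  counted <- logical(n)
  for (a in ones) for (b in ones[ones >= a]) {
    if (b - a + 1L < min_span) next
    seg <- bits[a:b]
    r <- rle(seg)
    interior_gaps <- r$lengths[r$values == 0L]
    if (length(interior_gaps) == 0L || max(interior_gaps) <= max_gap) {
      counted[a:b] <- TRUE
    }
  }
  sum(bits == 1L & counted)
}

# same quantity via fixed-length windows: any qualifying segment can be shrunk
# (each shrink removes at most max_gap+1 minutes) to one of span
# min_span..min_span+max_gap, so only those window lengths need checking
oracle_bout_minutes_windows <- function(bits, max_gap = 2L, min_span = 10L) {
  n <- length(bits)
  counted <- logical(n)
  for (L in min_span:(min_span + max_gap)) {
    if (L > n) break
    for (a in seq_len(n - L + 1L)) {
      b <- a + L - 1L
      if (bits[a] == 1L && bits[b] == 1L) {
        r <- rle(bits[a:b])
        gaps <- r$lengths[r$values == 0L]
        if (length(gaps) == 0L || max(gaps) <= max_gap) counted[a:b] <- TRUE
      }
    }
  }
  sum(bits == 1L & counted)
}

# weekly binary trace with one day's pattern placed on day 1, zero elsewhere
weekly_bits <- function(day1_bits) {
  c(day1_bits, rep(0L, MPW - length(day1_bits) - 0L))[seq_len(MPW)]
}

# --- exhaustive k-means oracle ----------------------------------------------

# global optimum WSS over all k=2 partitions of n <= 20 points (bitmask scan)
oracle_best_wss_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- as.integer(intToBits(mask))[1:n]
    wss <- 0
    for (j in 0:1) {
      xs <- x[g == j, , drop = FALSE]
      if (nrow(xs) == 0L) { wss <- Inf; break }
      wss <- wss + sum(sweep(xs, 2L, colMeans(xs))^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# all binary strings of length len as a matrix (rows = strings)
all_bitstrings <- function(len) {
  m <- t(sapply(0:(2^len - 1), function(v) as.integer(intToBits(v))[seq_len(len)]))
  storage.mode(m) <- "integer"
  m
}

# --- vectorized oracles over many strings at once ---------------------------

# rows of B are independent binary strings; returns per-row 5-min-criterion
# minutes via explicit window coverage
oracle_run_minutes_mat <- function(B, min_run = 5L) {
  n <- ncol(B)
  covered <- matrix(FALSE, nrow(B), n)
  for (a in seq_len(n - min_run + 1L)) {
    ok <- rowSums(B[, a:(a + min_run - 1L), drop = FALSE]) == min_run
    covered[, a:(a + min_run - 1L)] <- covered[, a:(a + min_run - 1L)] | ok
  }
  rowSums(B == 1L & covered)
}

# per-row bridged-bout minutes by enumerating endpoint pairs (a, b): both ends
# one-bits, span >= min_span, and no run of max_gap+1 zeros inside
oracle_bout_minutes_mat_pairs <- function(B, max_gap = 2L, min_span = 10L) {
  n <- ncol(B)
  Z <- B == 0L
  g <- max_gap + 1L
  # T[, i] = TRUE iff positions i..i+max_gap are all zero
  T <- matrix(TRUE, nrow(B), n - max_gap)
  for (d in 0:max_gap) T <- T & Z[, (1L + d):(n - max_gap + d), drop = FALSE]
  cumT <- t(apply(T, 1L, cumsum))
  any_bad <- function(a, b) {
    hi <- b - max_gap
    if (hi < a) return(rep(FALSE, nrow(B)))
    tot <- cumT[, hi]
    if (a > 1L) tot <- tot - cumT[, a - 1L]
    tot > 0
  }
  counted <- matrix(FALSE, nrow(B), n)
  for (a in seq_len(n)) {
    bs <- seq_len(n)
    bs <- bs[bs - a + 1L >= min_span]
    for (b in bs) {
      ok <- B[, a] == 1L & B[, b] == 1L & !any_bad(a, b)
      if (any(ok)) counted[, a:b] <- counted[, a:b] | ok
    }
  }
  rowSums(B == 1L & counted)
}

# same, but only windows of span min_span..min_span+max_gap (any qualifying
# segment shrinks into one of these); validated against the pair oracle
oracle_bout_minutes_mat_windows <- function(B, max_gap = 2L, min_span = 10L) {
  n <- ncol(B)
  Z <- B == 0L
  T <- matrix(TRUE, nrow(B), n - max_gap)
  for (d in 0:max_gap) T <- T & Z[, (1L + d):(n - max_gap + d), drop = FALSE]
  cumT <- t(apply(T, 1L, cumsum))
  counted <- matrix(FALSE, nrow(B), n)
  for (L in min_span:(min_span + max_gap)) {
    if (L > n) break
    for (a in seq_len(n - L + 1L)) {
      b <- a + L - 1L
      hi <- b - max_gap
      bad <- if (hi >= a) {
        tot <- cumT[, hi]
        if (a > 1L) tot <- tot - cumT[, a - 1L]
        tot > 0
      } else rep(FALSE, nrow(B))
      ok <- B[, a] == 1L & B[, b] == 1L & !bad
      if (any(ok)) counted[, a:b] <- counted[, a:b] | ok
    }
  }
  rowSums(B == 1L & counted)
}

# weekly trace whose day 1 is `bits` (padded with zeros) and other days zero
day1_week <- function(bits) {
  out <- rep(0L, MPW)
  out[seq_along(bits)] <- bits
  out
}

# subset a cohort to given participant ids
cohort_subset_ids <- function(cohort, ids) {
  cohort_dataset(cohort$traces[ids],
                 cohort$covariates[cohort$covariates$participant_id %in% ids, ,
                                   drop = FALSE])
}
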