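#' Weekly MVPA minutes, 1-minute criterion
#'
#' Every MVPA minute counts, regardless of whether it is part of a sustained
#' episode.
#'
#' @param binary 0/1 vector of length 10,080 from [binarize_mvpa()].
#' @return Total MVPA minutes over the week.
#' @export
mvpa_minutes_1min <- function(binary) {
  stopifnot(length(binary) == MINUTES_PER_WEEK, all(binary %in% c(0L, 1L)))
  sum(binary)
}

#' Weekly MVPA minutes, 5-minute criterion
#'
#' Counts MVPA minutes lying in maximal runs of at least 5 consecutive MVPA
#' minutes. Runs never span the midnight day boundary (the device resets at
#' midnight).
#'
#' @inheritParams mvpa_minutes_1min
#' @param min_run Minimum run length, default 5.
#' @return MVPA minutes inside qualifying runs.
#' @export
mvpa_minutes_5min <- function(binary, min_run = 5L) {
  stopifnot(length(binary) == MINUTES_PER_WEEK, all(binary %in% c(0L, 1L)))
  sum(vapply(split_days(binary), day_run_minutes, numeric(1), min_run = min_run))
}

#' Weekly MVPA minutes, 10-minute criterion with interruption allowance
#'
#' Within each day, every maximal gap of at most `max_gap_run` consecutive
#' sub-threshold minutes lying strictly between MVPA minutes is bridged; a
#' bout is a maximal bridged segment whose span (first to last MVPA minute)
#' is at least `min_span` minutes. Only MVPA minutes inside qualifying bouts
#' are counted — bridged interruption minutes are not. Bouts never span
#' midnight.
#'
#' An alternative sliding-window reading (`method = "window"`) counts MVPA
#' minutes covered by some 10-minute window containing at least
#' `min_span - max_gap_run` MVPA minutes; it is provided for sensitivity
#' analysis and is not the default.
#'
#' @inheritParams mvpa_minutes_1min
#' @param max_gap_run Longest tolerated interruption, default 2 minutes.
#' @param min_span Minimum bout span, default 10 minutes.
#' @param method `"bridged"` (default) or `"window"`.
#' @return MVPA minutes inside qualifying bouts.
#' @export
mvpa_minutes_10min <- function(binary, max_gap_run = 2L, min_span = 10L,
                               method = c("bridged", "window")) {
  method <- match.arg(method)
  stopifnot(length(binary) == MINUTES_PER_WEEK, all(binary %in% c(0L, 1L)),
            max_gap_run >= 0L, min_span >= 1L)
  f <- if (method == "bridged") day_bouts_bridged else day_bouts_window
  sum(vapply(split_days(binary), f, numeric(1),
             max_gap_run = max_gap_run, min_span = min_span))
}

split_days <- function(binary) {
  split(as.integer(binary), rep(seq_len(DAYS_PER_WEEK), each = MINUTES_PER_DAY))
}

# single-day engine for the 5-minute (consecutive-run) criterion
day_run_minutes <- function(day, min_run) {
  r <- rle(day)
  sum(r$lengths[r$values == 1L & r$lengths >= min_run])
}

day_bouts_bridged <- function(day, max_gap_run, min_span) {
  r <- rle(day)
  n_runs <- length(r$lengths)
  if (!any(r$values == 1L)) return(0)
  # a zero-run merges its neighbours iff it is short and strictly interior
  merges <- r$values == 0L & r$lengths <= max_gap_run &
    seq_len(n_runs) > 1L & seq_len(n_runs) < n_runs
  # segment id advances at every non-merging zero-run
  seg <- cumsum(r$values == 0L & !merges)
  total <- 0
  for (s in unique(seg[r$values == 1L])) {
    runs <- which(seg == s & (r$values == 1L | merges))
    span <- sum(r$lengths[runs])
    if (span >= min_span) total <- total + sum(r$lengths[runs[r$values[runs] == 1L]])
  }
  total
}

day_bouts_window <- function(day, max_gap_run, min_span) {
  n <- length(day)
  if (n < min_span) return(0)
  csum <- cumsum(day)
  win <- csum[min_span:n] - c(0, csum)[1:(n - min_span + 1L)]
  ok <- win >= (min_span - max_gap_run)
  if (!any(ok)) return(0)
  covered <- logical(n)
  for (a in which(ok)) covered[a:(a + min_span - 1L)] <- TRUE
  sum(day == 1L & covered)
}

#' Mean daily steps
#'
#' Sum of observed step counts over the week divided by 7 (every retained
#' participant contributes 7 valid days, so the denominator is fixed).
#'
#' @param trace A `participant_trace`.
#' @return Steps per day, or `NA` when the steps channel is absent.
#' @export
mean_daily_steps <- function(trace) {
  stopifnot(is_participant_trace(trace))
  if (is.null(trace$steps)) return(NA_real_)
  sum(trace$steps, na.rm = TRUE) / DAYS_PER_WEEK
}

#' Per-participant bout summary table
#'
#' Weekly MVPA minutes under the 1-, 5- and 10-minute criteria plus mean
#' daily steps, one row per participant (sorted by id).
#'
#' @param cohort A `cohort_dataset`.
#' @param threshold MVPA MET threshold, default 3.
#' @param max_gap_run Interruption allowance for the 10-minute criterion.
#' @return Data frame with columns `participant_id`, `weekly_mvpa_1min`,
#'   `weekly_mvpa_5min`, `weekly_mvpa_10min`, `mean_daily_steps`.
#' @export
bout_summary <- function(cohort, threshold = 3.0, max_gap_run = 2L) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  ids <- participant_ids(cohort)
  rows <- lapply(ids, function(i) {
    tr <- cohort$traces[[i]]
    b <- binarize_mvpa(tr, threshold)
    data.frame(participant_id = i,
               weekly_mvpa_1min = mvpa_minutes_1min(b),
               weekly_mvpa_5min = mvpa_minutes_5min(b),
               weekly_mvpa_10min = mvpa_minutes_10min(b, max_gap_run),
               mean_daily_steps = mean_daily_steps(tr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
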