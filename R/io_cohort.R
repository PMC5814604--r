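#' Read a minute-level accelerometer cohort from CSV
#'
#' Two dialects are supported. Long format has one row per observed
#' participant-minute with columns `participant_id, day, minute, mets[, steps]`
#' (`day` in 1..7, `minute` in 0..1439; an empty/NA `mets` cell or an absent
#' row both mean the minute is missing). Wide format has one row per
#' participant-day with columns `participant_id, day, m0000..m1439`. Missing
#' minutes are kept missing — never fabricated as zeros.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param format `"long_csv"` or `"wide_csv"`.
#' @param covariates Optional data frame of covariates keyed by
#'   `participant_id`, attached to the returned cohort.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(path, format = c("long_csv", "wide_csv"), covariates = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, na.strings = c("", "NA"))
  if (format == "long_csv") {
    traces <- parse_long(dt)
  } else {
    traces <- parse_wide(dt)
  }
  cohort_dataset(traces, covariates)
}

parse_long <- function(dt) {
  need <- c("participant_id", "day", "minute", "mets")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("long CSV missing columns: ", paste(miss, collapse = ", "))
  has_steps <- "steps" %in% names(dt)
  day <- as.integer(dt[["day"]])
  minute <- as.integer(dt[["minute"]])
  bad_day <- which(is.na(day) | day < 1L | day > DAYS_PER_WEEK)
  if (length(bad_day)) {
    stop("day outside 1-7 at data row ", bad_day[1])
  }
  bad_min <- which(is.na(minute) | minute < 0L | minute >= MINUTES_PER_DAY)
  if (length(bad_min)) {
    stop("minute outside 0-1439 at data row ", bad_min[1])
  }
  id <- as.character(dt[["participant_id"]])
  pos <- (day - 1L) * MINUTES_PER_DAY + minute + 1L
  key <- paste(id, pos)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, day, minute) cell at data row ",
         which(duplicated(key))[1])
  }
  mets <- as.numeric(dt[["mets"]])
  bad_met <- which(!is.na(mets) & (!is.finite(mets) | mets < 0))
  if (length(bad_met)) {
    stop("invalid MET value (must be finite and >= 0) at data row ", bad_met[1])
  }
  ids <- unique(id)
  lapply(ids, function(i) {
    sel <- id == i
    m <- rep(NA_real_, MINUTES_PER_WEEK)
    m[pos[sel]] <- mets[sel]
    s <- NULL
    if (has_steps) {
      sv <- as.numeric(dt[["steps"]])
      if (any(!is.na(sv[sel]))) {
        s <- rep(NA_real_, MINUTES_PER_WEEK)
        s[pos[sel]] <- sv[sel]
      }
    }
    participant_trace(i, m, s)
  })
}

parse_wide <- function(dt) {
  mcols <- sprintf("m%04d", 0:(MINUTES_PER_DAY - 1L))
  miss <- setdiff(c("participant_id", "day", mcols), names(dt))
  if (length(miss)) stop("wide CSV missing columns: ", miss[1], " ...")
  id <- as.character(dt[["participant_id"]])
  day <- as.integer(dt[["day"]])
  bad_day <- which(is.na(day) | day < 1L | day > DAYS_PER_WEEK)
  if (length(bad_day)) stop("day outside 1-7 at data row ", bad_day[1])
  if (anyDuplicated(paste(id, day))) {
    stop("duplicate (participant, day) row at data row ",
         which(duplicated(paste(id, day)))[1])
  }
  vals <- as.matrix(dt[, mcols, with = FALSE])
  storage.mode(vals) <- "double"
  if (any(!is.na(vals) & (!is.finite(vals) | vals < 0))) {
    stop("invalid MET value (must be finite and >= 0) in wide CSV")
  }
  ids <- unique(id)
  lapply(ids, function(i) {
    m <- rep(NA_real_, MINUTES_PER_WEEK)
    for (r in which(id == i)) {
      m[((day[r] - 1L) * MINUTES_PER_DAY + 1L):(day[r] * MINUTES_PER_DAY)] <- vals[r, ]
    }
    participant_trace(i, m)
  })
}

#' Write a cohort to a long-format CSV
#'
#' Emits only observed minutes (missing minutes are represented by absence),
#' so the file round-trips through [read_cohort()].
#'
#' @param cohort A `cohort_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_long <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  parts <- lapply(cohort$traces, function(tr) {
    obs <- which(!is.na(tr$mets))
    clk <- trace_clock(obs)
    out <- data.table::data.table(participant_id = tr$participant_id,
                                  day = clk$day, minute = clk$minute,
                                  mets = tr$mets[obs])
    if (!is.null(tr$steps)) out$steps <- tr$steps[obs]
    out
  })
  data.table::fwrite(data.table::rbindlist(parts, fill = TRUE), path)
  invisible(path)
}

#' Observed wear minutes per day
#'
#' A minute counts as worn iff its MET value is non-missing (the device
#' records only while worn; no separate non-wear algorithm is applied).
#'
#' @param trace A `participant_trace`.
#' @return Integer vector of length 7, each entry in 0..1440.
#' @export
wear_minutes_per_day <- function(trace) {
  stopifnot(is_participant_trace(trace))
  worn <- !is.na(trace$mets)
  as.integer(colSums(matrix(worn, nrow = MINUTES_PER_DAY, ncol = DAYS_PER_WEEK)))
}

#' Filter a cohort by the wear-time validity rule
#'
#' Retains exactly the participants whose every one of the 7 days has at
#' least `min_hours_per_day` hours of recorded wear. The default reproduces
#' the trial rule: all 7 days with >= 8 h (480 min) of wear.
#'
#' @param cohort A `cohort_dataset`.
#' @param min_hours_per_day Minimum wear hours required on every day.
#' @param required_days Number of days that must each satisfy the minimum.
#' @return A list with `cohort` (the surviving `cohort_dataset`) and
#'   `exclusions`, a data frame with columns `participant_id`, `reason`,
#'   `first_failing_day`.
#' @export
filter_valid_participants <- function(cohort, min_hours_per_day = 8, required_days = 7L) {
  stopifnot(inherits(cohort, "cohort_dataset"), required_days >= 1L,
            required_days <= DAYS_PER_WEEK)
  min_minutes <- min_hours_per_day * 60
  verdicts <- lapply(cohort$traces, function(tr) {
    wear <- wear_minutes_per_day(tr)
    failing <- which(wear < min_minutes)
    # valid iff at least required_days days meet the minimum (default: all 7)
    if (DAYS_PER_WEEK - length(failing) >= required_days) NULL else failing[1]
  })
  excluded <- !vapply(verdicts, is.null, logical(1))
  exclusions <- data.frame(
    participant_id = names(cohort$traces)[excluded],
    reason = sprintf("wear < %g min on day %d", min_minutes,
                     unlist(verdicts[excluded], use.names = FALSE)),
    first_failing_day = unlist(verdicts[excluded], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(exclusions) == 0L) {
    exclusions <- data.frame(participant_id = character(), reason = character(),
                             first_failing_day = integer(), stringsAsFactors = FALSE)
  }
  keep <- names(cohort$traces)[!excluded]
  if (length(keep) == 0L) {
    stop("no participant satisfies the wear-validity rule (",
         min_hours_per_day, " h on each of ", required_days,
         " days); review the threshold or the input data")
  }
  surviving <- cohort_dataset(
    cohort$traces[keep],
    cohort$covariates[cohort$covariates$participant_id %in% keep, , drop = FALSE]
  )
  list(cohort = surviving, exclusions = exclusions)
}

#' Impute missing minutes with a stationary MET value
#'
#' Missing minutes (mostly overnight non-wear) are replaced by the METs
#' reading of a stationary individual, 1.0 by default. Observed values are
#' never altered.
#'
#' @param trace A `participant_trace`.
#' @param fill_value MET value written into missing minutes.
#' @return A complete `participant_trace` (no missing MET entries).
#' @export
impute_missing <- function(trace, fill_value = 1.0) {
  stopifnot(is_participant_trace(trace), is.finite(fill_value), fill_value >= 0)
  m <- trace$mets
  m[is.na(m)] <- fill_value
  participant_trace(trace$participant_id, m, trace$steps)
}
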