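#' @importFrom stats rnorm rpois sd lm anova chisq.test t.test loess predict
#' @importFrom utils write.csv
NULL

MINUTES_PER_DAY <- 1440L
DAYS_PER_WEEK <- 7L
MINUTES_PER_WEEK <- MINUTES_PER_DAY * DAYS_PER_WEEK # 10,080

#' Construct a participant trace
#'
#' A participant trace holds one subject's week of minute-level accelerometer
#' data: 10,080 MET values (7 days x 1440 minutes), with `NA` marking minutes
#' in which the device recorded nothing (non-wear), plus an optional parallel
#' step-count channel. Minute 0 of each day is local midnight; the device day
#' boundary is midnight.
#'
#' @param participant_id Single character id.
#' @param mets Numeric vector of length 10,080. `NA` = missing (non-wear);
#'   observed values must be finite and `>= 0` (METs are multiples of resting
#'   metabolic rate, so 1 is quiet sitting).
#' @param steps Optional integer vector of length 10,080 of non-negative
#'   per-minute step counts (`NA` where missing), or `NULL` when the channel
#'   is absent.
#' @return An object of class `participant_trace`.
#' @export
participant_trace <- function(participant_id, mets, steps = NULL) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            !is.na(participant_id), nzchar(participant_id))
  mets <- as.numeric(mets)
  if (length(mets) != MINUTES_PER_WEEK) {
    stop("mets must have length ", MINUTES_PER_WEEK, " (7 days x 1440 minutes), got ",
         length(mets))
  }
  obs <- mets[!is.na(mets)]
  if (any(!is.finite(obs)) || any(obs < 0)) {
    stop("observed MET values must be finite and >= 0 for participant ", participant_id)
  }
  if (!is.null(steps)) {
    steps <- as.numeric(steps)
    if (length(steps) != MINUTES_PER_WEEK) {
      stop("steps must have length ", MINUTES_PER_WEEK, ", got ", length(steps))
    }
    sobs <- steps[!is.na(steps)]
    if (any(!is.finite(sobs)) || any(sobs < 0)) {
      stop("observed step counts must be finite and >= 0 for participant ", participant_id)
    }
  }
  structure(list(participant_id = participant_id, mets = mets, steps = steps),
            class = "participant_trace")
}

#' @export
print.participant_trace <- function(x, ...) {
  wear <- sum(!is.na(x$mets))
  cat(sprintf("<participant_trace> %s: %d/%d minutes observed, steps %s\n",
              x$participant_id, wear, MINUTES_PER_WEEK,
              if (is.null(x$steps)) "absent" else "present"))
  invisible(x)
}

is_participant_trace <- function(x) inherits(x, "participant_trace")

#' Day index and minute-of-day of each trace position
#'
#' Positions are 1-based in R; position `t` maps to day `((t-1) %/% 1440) + 1`
#' (1..7) and minute-of-day `(t-1) %% 1440` (0..1439, 0 = midnight).
#'
#' @param t Integer vector of trace positions in 1..10,080.
#' @return Data frame with columns `day` and `minute`.
#' @export
trace_clock <- function(t) {
  stopifnot(all(t >= 1L), all(t <= MINUTES_PER_WEEK))
  data.frame(day = ((t - 1L) %/% MINUTES_PER_DAY) + 1L,
             minute = (t - 1L) %% MINUTES_PER_DAY)
}

#' Construct a cohort dataset
#'
#' Bundles a set of participant traces with a covariate table keyed by
#' `participant_id`. Every trace id must appear in the covariate table;
#' covariate rows without a trace are allowed but flagged with a warning.
#'
#' @param traces List of `participant_trace` objects.
#' @param covariates Data frame with a `participant_id` column; other columns
#'   are numeric or factor/character covariates. Defaults to an id-only table.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(traces, covariates = NULL) {
  stopifnot(is.list(traces), all(vapply(traces, is_participant_trace, logical(1))))
  ids <- vapply(traces, function(tr) tr$participant_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate participant ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(traces) <- ids
  if (is.null(covariates)) {
    covariates <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(covariates), "participant_id" %in% names(covariates))
  covariates$participant_id <- as.character(covariates$participant_id)
  if (anyDuplicated(covariates$participant_id)) {
    stop("duplicate participant_id rows in covariate table")
  }
  missing_cov <- setdiff(ids, covariates$participant_id)
  if (length(missing_cov)) {
    stop("traces without covariate rows: ", paste(missing_cov, collapse = ", "))
  }
  extras <- setdiff(covariates$participant_id, ids)
  if (length(extras)) {
    warning("covariate rows without traces (kept): ", paste(extras, collapse = ", "))
  }
  structure(list(traces = traces, covariates = covariates), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d participants, %d covariate columns\n",
              length(x$traces), ncol(x$covariates) - 1L))
  invisible(x)
}

#' Participant ids of a cohort, sorted
#' @param cohort A `cohort_dataset`.
#' @return Character vector of ids in sorted order.
#' @export
participant_ids <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  sort(names(cohort$traces))
}
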