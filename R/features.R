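#' Feature matrix constructor
#'
#' A feature matrix is an n x p numeric matrix with participant ids as row
#' names and a `kind` attribute: `"raw"` (p = 10,080 imputed minute-level
#' METs) or `"normalized_mvpa"` (p = 1440 unit-normalized MVPA-frequency
#' profiles).
#'
#' @param values Numeric matrix, rows = participants.
#' @param kind `"raw"` or `"normalized_mvpa"`.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, kind = c("raw", "normalized_mvpa")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), is.numeric(values), !is.null(rownames(values)))
  p_expected <- if (kind == "raw") MINUTES_PER_WEEK else MINUTES_PER_DAY
  if (ncol(values) != p_expected) {
    stop(kind, " feature matrix must have ", p_expected, " columns, got ", ncol(values))
  }
  if (anyNA(values) || any(values < 0)) {
    stop("feature matrix entries must be non-missing and >= 0")
  }
  structure(values, kind = kind, class = c("feature_matrix", class(values)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> kind=%s, %d participants x %d features\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

feature_kind <- function(x) attr(x, "kind")

#' Raw minute-level MET feature matrix
#'
#' One row per participant: the full week of minute-level METs in time order
#' (10,080 features), with missing minutes imputed to the stationary value 1.
#' Rows are ordered by sorted participant id. The cohort must already have
#' passed the wear-validity filter.
#'
#' @param cohort A validity-filtered `cohort_dataset`.
#' @param fill_value Imputation value for missing minutes.
#' @return A `feature_matrix` of kind `"raw"`.
#' @export
raw_feature_matrix <- function(cohort, fill_value = 1.0) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  check_filtered(cohort)
  ids <- participant_ids(cohort)
  values <- t(vapply(ids, function(i) impute_missing(cohort$traces[[i]], fill_value)$mets,
                     numeric(MINUTES_PER_WEEK)))
  rownames(values) <- ids
  feature_matrix(values, "raw")
}

check_filtered <- function(cohort) {
  wear_ok <- vapply(cohort$traces,
                    function(tr) all(wear_minutes_per_day(tr) >= 480L), logical(1))
  if (!all(wear_ok)) {
    stop("cohort contains participants failing the 8 h/day wear rule; ",
         "run filter_valid_participants() first: ",
         paste(names(cohort$traces)[!wear_ok], collapse = ", "))
  }
  invisible(TRUE)
}

#' Binarize a trace at the MVPA threshold
#'
#' Minute t maps to 1 iff its observed MET value is at or above `threshold`
#' (3 METs marks moderate intensity); missing minutes map to 0, which
#' coincides with imputing 1 MET and then thresholding since 1 < 3.
#'
#' @param trace A `participant_trace`.
#' @param threshold MET cut point, default 3.
#' @return Integer 0/1 vector of length 10,080.
#' @export
binarize_mvpa <- function(trace, threshold = 3.0) {
  stopifnot(is_participant_trace(trace))
  bits <- as.integer(!is.na(trace$mets) & trace$mets >= threshold)
  bits
}

#' Average a binary MVPA trace over the 7 days
#'
#' Entry m (0-based minute-of-day) is the fraction of the 7 days on which the
#' participant was in MVPA at that minute, so entries lie in {0, 1/7, ..., 1}.
#'
#' @param binary 0/1 vector of length 10,080 (see [binarize_mvpa()]).
#' @return Numeric vector of length 1440: the typical-day MVPA frequency.
#' @export
daily_average_profile <- function(binary) {
  stopifnot(length(binary) == MINUTES_PER_WEEK, all(binary %in% c(0L, 1L)))
  rowMeans(matrix(as.numeric(binary), nrow = MINUTES_PER_DAY, ncol = DAYS_PER_WEEK))
}

#' Scale a profile to unit Euclidean norm
#'
#' Dividing by the Euclidean norm removes overall activity volume so that
#' clustering sees only the within-day timing of MVPA. A participant with no
#' MVPA at all has a zero profile that cannot be normalized; the zero vector
#' is returned with attribute `degenerate = TRUE` rather than an error.
#'
#' @param profile Non-negative numeric vector.
#' @return The unit-normalized vector, or the input zero vector carrying
#'   attribute `degenerate = TRUE`.
#' @export
unit_normalize <- function(profile) {
  stopifnot(is.numeric(profile), all(is.finite(profile)), all(profile >= 0))
  nrm <- sqrt(sum(profile^2))
  if (nrm == 0) {
    attr(profile, "degenerate") <- TRUE
    return(profile)
  }
  profile / nrm
}

#' Test the degenerate (zero-MVPA) flag
#' @param x Result of [unit_normalize()].
#' @return `TRUE` iff the profile was all zero.
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

#' Normalized MVPA-frequency feature matrix
#'
#' Per participant: binarize at the MVPA threshold, average the 7 days into a
#' 1440-minute typical-day frequency profile, and scale to unit Euclidean
#' norm. Participants with zero MVPA minutes have no direction and are either
#' excluded (default, reported) or kept as all-zero rows.
#'
#' @param cohort A validity-filtered `cohort_dataset`.
#' @param degenerate_policy `"exclude"` or `"keep_zero"`.
#' @param threshold MVPA MET threshold, default 3.
#' @return List with `features` (a `feature_matrix` of kind
#'   `"normalized_mvpa"`, rows sorted by id) and `degenerate_ids`.
#' @export
normalized_feature_matrix <- function(cohort,
                                      degenerate_policy = c("exclude", "keep_zero"),
                                      threshold = 3.0) {
  degenerate_policy <- match.arg(degenerate_policy)
  stopifnot(inherits(cohort, "cohort_dataset"))
  check_filtered(cohort)
  ids <- participant_ids(cohort)
  rows <- lapply(ids, function(i) {
    unit_normalize(daily_average_profile(binarize_mvpa(cohort$traces[[i]], threshold)))
  })
  degenerate <- vapply(rows, is_degenerate, logical(1))
  degenerate_ids <- ids[degenerate]
  if (all(degenerate)) {
    stop("every participant has zero MVPA minutes at threshold ", threshold,
         "; no normalized features can be built")
  }
  if (degenerate_policy == "exclude") {
    rows <- rows[!degenerate]
    ids <- ids[!degenerate]
  }
  values <- do.call(rbind, lapply(rows, as.numeric))
  rownames(values) <- ids
  list(features = feature_matrix(values, "normalized_mvpa"),
       degenerate_ids = degenerate_ids)
}

#' Write a feature matrix to CSV with a sidecar JSON
#'
#' @param features A `feature_matrix`.
#' @param path Output CSV path; a `.json` sidecar recording the kind is
#'   written next to it.
#' @param meta Extra fields merged into the sidecar (threshold, policy, ...).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path, meta = list()) {
  stopifnot(inherits(features, "feature_matrix"))
  dt <- data.table::data.table(participant_id = rownames(features))
  dt <- cbind(dt, data.table::as.data.table(unclass(features)))
  data.table::fwrite(dt, path)
  sidecar <- c(list(kind = feature_kind(features),
                    n = nrow(features), p = ncol(features)), meta)
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
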