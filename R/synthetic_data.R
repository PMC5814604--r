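#' Archetype specification for the synthetic generator
#'
#' An archetype is a daily activity shape: a sedentary baseline plus one or
#' more Gaussian activity bumps. A bump contributes
#' `(peak_mets - baseline_mean) * mvpa_prob_scale * exp(-(m - peak)^2 / (2 width^2))`
#' METs at minute-of-day `m`, with the peak position jittered day to day.
#'
#' @param name Archetype name (becomes the planted label).
#' @param windows Data frame with columns `peak` (minute-of-day, 0..1439),
#'   `width` (minutes, > 0) and `peak_mets` (>= baseline). May have 0 rows
#'   for a purely sedentary archetype.
#' @param baseline_mean Sedentary MET level, default 1.2.
#' @param baseline_sd Minute-to-minute sedentary fluctuation (MET SD).
#' @param mvpa_prob_scale Multiplier on bump intensity; 1 = as specified.
#' @param day_jitter_sd SD (minutes) of the daily jitter on each peak time.
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, windows, baseline_mean = 1.2, baseline_sd = 0.25,
                           mvpa_prob_scale = 1, day_jitter_sd = 30) {
  stopifnot(is.character(name), length(name) == 1L, is.data.frame(windows),
            all(c("peak", "width", "peak_mets") %in% names(windows)) || nrow(windows) == 0L)
  if (nrow(windows) > 0L) {
    stopifnot(all(windows$peak >= 0), all(windows$peak < MINUTES_PER_DAY),
              all(windows$width > 0), all(windows$peak_mets >= baseline_mean))
  }
  stopifnot(baseline_mean >= 0, baseline_sd >= 0, mvpa_prob_scale >= 0,
            day_jitter_sd >= 0)
  structure(list(name = name, windows = windows, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, mvpa_prob_scale = mvpa_prob_scale,
                 day_jitter_sd = day_jitter_sd),
            class = "archetype_spec")
}

#' Synthetic cohort configuration
#'
#' @param n_participants Cohort size.
#' @param archetypes List of [archetype_spec()] objects.
#' @param proportions Mixture proportions (same length, sums to 1).
#' @param wake,bed Minutes-of-day bounding daily wear; minutes outside
#'   `[wake, bed)` are stored as missing (overnight non-wear).
#' @param wake_jitter_sd SD (minutes) of daily jitter on wake and bed times.
#' @param noise_sd Additional measurement-noise SD on observed METs.
#' @param step_rate Steps per minute per MET above 1.3 (plus a sedentary
#'   base of 3/min); set `NULL` to omit the steps channel.
#' @param covariates Covariate generation spec: a list of per-variable specs,
#'   each either `list(type="continuous", mean=<per-archetype vector>, sd=)`
#'   or `list(type="categorical", levels=, probs=<archetype x level matrix>)`.
#' @param seed RNG seed making generation deterministic.
#' @return An object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_participants, archetypes, proportions,
                                    wake = 360L, bed = 1320L, wake_jitter_sd = 20,
                                    noise_sd = 0.15, step_rate = 15,
                                    covariates = list(), seed = 1L) {
  stopifnot(n_participants >= 1L, length(archetypes) == length(proportions),
            all(vapply(archetypes, inherits, logical(1), "archetype_spec")),
            all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  stopifnot(wake >= 0, bed > wake, bed <= MINUTES_PER_DAY)
  structure(list(n_participants = as.integer(n_participants),
                 archetypes = archetypes, proportions = proportions,
                 wake = as.integer(wake), bed = as.integer(bed),
                 wake_jitter_sd = wake_jitter_sd, noise_sd = noise_sd,
                 step_rate = step_rate, covariates = covariates,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

# largest-remainder apportionment of n among proportions
apportion <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1L
  }
  as.integer(counts)
}

#' Generate a synthetic minute-level accelerometer cohort
#'
#' Each participant is assigned an archetype (exact largest-remainder counts
#' per the mixture proportions, in shuffled order); each day's METs are the
#' archetype baseline plus jittered Gaussian activity bumps plus Gaussian
#' noise, truncated at 0; minutes outside the (jittered) wake-bed window are
#' missing. Steps, when enabled, are Poisson with rate increasing in METs.
#' Covariates are drawn with archetype-specific distributions so that
#' downstream group comparisons have signal. Deterministic given the seed.
#'
#' @param config A [synthetic_cohort_config()].
#' @return List with `cohort` (a [cohort_dataset()]) and `labels` (character
#'   vector of planted archetype names, named by participant id).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  arch_names <- vapply(config$archetypes, function(a) a$name, character(1))
  counts <- apportion(n, config$proportions)
  assignment <- sample(rep(seq_along(config$archetypes), counts))
  ids <- sprintf("P%04d", seq_len(n))

  traces <- vector("list", n)
  for (i in seq_len(n)) {
    a <- config$archetypes[[assignment[i]]]
    traces[[i]] <- simulate_trace(ids[i], a, config)
  }
  labels <- arch_names[assignment]
  names(labels) <- ids
  covariates <- simulate_covariates(ids, assignment, config)
  list(cohort = cohort_dataset(traces, covariates), labels = labels)
}

simulate_trace <- function(id, arch, config) {
  m <- 0:(MINUTES_PER_DAY - 1L)
  sd_total <- sqrt(arch$baseline_sd^2 + config$noise_sd^2)
  mets <- numeric(0)
  steps <- numeric(0)
  for (day in seq_len(DAYS_PER_WEEK)) {
    day_mets <- arch$baseline_mean + rnorm(MINUTES_PER_DAY, 0, sd_total)
    if (nrow(arch$windows) > 0L) {
      for (w in seq_len(nrow(arch$windows))) {
        peak <- arch$windows$peak[w] + rnorm(1, 0, arch$day_jitter_sd)
        amp <- (arch$windows$peak_mets[w] - arch$baseline_mean) * arch$mvpa_prob_scale
        day_mets <- day_mets + amp * exp(-(m - peak)^2 / (2 * arch$windows$width[w]^2))
      }
    }
    day_mets <- pmax(day_mets, 0)
    wake <- max(0L, round(config$wake + rnorm(1, 0, config$wake_jitter_sd)))
    bed <- min(MINUTES_PER_DAY, round(config$bed + rnorm(1, 0, config$wake_jitter_sd)))
    worn <- m >= wake & m < bed
    day_mets[!worn] <- NA_real_
    if (!is.null(config$step_rate)) {
      lam <- 3 + config$step_rate * pmax(day_mets - 1.3, 0)
      day_steps <- rep(NA_real_, MINUTES_PER_DAY)
      day_steps[worn] <- rpois(sum(worn), lam[worn])
      steps <- c(steps, day_steps)
    }
    mets <- c(mets, day_mets)
  }
  participant_trace(id, mets, if (is.null(config$step_rate)) NULL else steps)
}

simulate_covariates <- function(ids, assignment, config) {
  cov <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (var in names(config$covariates)) {
    spec <- config$covariates[[var]]
    if (spec$type == "continuous") {
      cov[[var]] <- rnorm(length(ids), mean = spec$mean[assignment], sd = spec$sd)
    } else {
      cov[[var]] <- vapply(assignment, function(a) {
        sample(spec$levels, 1L, prob = spec$probs[a, ])
      }, character(1))
    }
  }
  cov
}

#' Default trial-sized cohort configuration
#'
#' Three diel archetypes over 215 participants in proportions 65:48:102 —
#' an afternoon-peaked engaged shape, a morning-peaked engaged shape, and a
#' low-activity ("unengaged") shape — with 16 h/day wear (06:00-22:00) and
#' overnight non-wear. Bump widths and heights are calibrated so that the
#' archetypes' expected weekly 1-minute-criterion MVPA lands near 372, 401
#' and 206 minutes respectively. Covariates include a depressive-symptom
#' score elevated in the unengaged archetype and mild anthropometric shifts,
#' giving the comparison module signal to detect.
#'
#' @param seed RNG seed for the generated cohort.
#' @return A [synthetic_cohort_config()].
#' @export
default_trial_config <- function(seed = 1L) {
  afternoon <- archetype_spec(
    "afternoon_engaged",
    data.frame(peak = 900, width = 21.6, peak_mets = 5.0),
    baseline_mean = 1.2, baseline_sd = 0.25, day_jitter_sd = 30)
  morning <- archetype_spec(
    "morning_engaged",
    data.frame(peak = 540, width = 23.4, peak_mets = 5.0),
    baseline_mean = 1.2, baseline_sd = 0.25, day_jitter_sd = 30)
  unengaged <- archetype_spec(
    "unengaged",
    data.frame(peak = 780, width = 28.8, peak_mets = 3.3),
    baseline_mean = 1.2, baseline_sd = 0.25, day_jitter_sd = 45)
  covariates <- list(
    age = list(type = "continuous", mean = c(52.4, 52.4, 52.4), sd = 11.2),
    cesd = list(type = "continuous", mean = c(10, 10, 15), sd = 8),
    bmi = list(type = "continuous", mean = c(29.5, 29.5, 31.0), sd = 5.2),
    education = list(type = "categorical",
                     levels = c("high_school", "college", "graduate"),
                     probs = rbind(c(0.35, 0.40, 0.25),
                                   c(0.35, 0.40, 0.25),
                                   c(0.20, 0.45, 0.35)))
  )
  synthetic_cohort_config(
    n_participants = 215L,
    archetypes = list(afternoon, morning, unengaged),
    proportions = c(65, 48, 102) / 215,
    wake = 360L, bed = 1320L, wake_jitter_sd = 20,
    noise_sd = 0.15, step_rate = 15,
    covariates = covariates, seed = seed)
}

#' Simulate the screening funnel in front of the validity filter
#'
#' Produces a pre-filter cohort: `n_valid` participants generated from
#' `config`, plus `n_runin_failures` participants with no recorded minutes at
#' all (they never completed the run-in) and `n_low_wear` participants with
#' one day degraded below 8 h of wear. Useful for exercising
#' [filter_valid_participants()] end to end.
#'
#' @param config Base [synthetic_cohort_config()] for the valid participants.
#' @param n_runin_failures Count of zero-wear participants appended.
#' @param n_low_wear Count of insufficient-wear participants appended.
#' @return List with `cohort` (size `n_valid + n_runin_failures + n_low_wear`)
#'   and `labels` (planted archetypes of the valid participants only).
#' @export
simulate_screening <- function(config, n_runin_failures = 57L, n_low_wear = 46L) {
  gen <- generate_cohort(config)
  traces <- gen$cohort$traces
  n0 <- length(traces)
  extra <- list()
  # run-in failures: device never worn in the analysis week
  for (i in seq_len(n_runin_failures)) {
    extra[[length(extra) + 1L]] <-
      participant_trace(sprintf("R%04d", i), rep(NA_real_, MINUTES_PER_WEEK))
  }
  # low-wear: a valid-looking trace with one day cut to under 8 h
  low_config <- config
  low_config$n_participants <- as.integer(n_low_wear)
  low_config$seed <- config$seed + 104729L # distinct stream, fixed offset
  low <- generate_cohort(low_config)
  set.seed(config$seed + 15485863L)
  for (i in seq_len(n_low_wear)) {
    tr <- low$cohort$traces[[i]]
    day <- sample.int(DAYS_PER_WEEK, 1L)
    idx <- ((day - 1L) * MINUTES_PER_DAY + 1L):(day * MINUTES_PER_DAY)
    keep <- sample(450:479, 1L) # wear just under the 480-minute rule
    worn <- which(!is.na(tr$mets[idx]))
    drop <- worn[-seq_len(min(keep, length(worn)))]
    tr$mets[idx][drop] <- NA_real_
    if (!is.null(tr$steps)) tr$steps[idx][drop] <- NA_real_
    tr$participant_id <- sprintf("L%04d", i)
    extra[[length(extra) + 1L]] <-
      participant_trace(tr$participant_id, tr$mets, tr$steps)
  }
  all_traces <- c(traces, extra)
  extra_ids <- vapply(extra, function(tr) tr$participant_id, character(1))
  covariates <- rbind(
    gen$cohort$covariates[, "participant_id", drop = FALSE],
    data.frame(participant_id = extra_ids, stringsAsFactors = FALSE))
  for (col in setdiff(names(gen$cohort$covariates), "participant_id")) {
    covariates[[col]] <- c(gen$cohort$covariates[[col]],
                           rep(NA, length(extra_ids)))
  }
  list(cohort = cohort_dataset(all_traces, covariates), labels = gen$labels,
       n_valid = n0)
}
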