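#' Run configuration for the full pipeline
#'
#' Exactly one of `input` (path to a long-format cohort CSV) or
#' `simulate = TRUE` (generate the default trial-sized synthetic cohort)
#' must be given.
#'
#' @param input Optional path to a long CSV readable by [read_cohort()].
#' @param covariates_csv Optional CSV of covariates keyed by `participant_id`,
#'   read alongside `input`; ignored when simulating.
#' @param simulate Generate a synthetic cohort instead of reading one.
#' @param feature_kind `"raw"`, `"normalized"` or `"both"`.
#' @param k Fixed number of clusters; `NULL` to choose by the elbow scan.
#' @param k_max Largest k scanned when `k` is `NULL` (>= 2).
#' @param restarts Random k-means restarts, default 25.
#' @param seed Master seed for all randomness.
#' @param span Loess span for the diel curves.
#' @param alpha Significance level for group comparisons.
#' @param out_dir Artifact directory (created if absent).
#' @param write_features Also write the (large) feature matrix CSVs.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, covariates_csv = NULL,
                       simulate = is.null(input),
                       feature_kind = c("both", "raw", "normalized"),
                       k = NULL, k_max = 6L, restarts = 25L, seed = 1L,
                       span = 0.1, alpha = 0.05, out_dir = "results",
                       write_features = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (is.null(input) == !isTRUE(simulate)) {
    stop("exactly one of `input` or `simulate` must be specified")
  }
  if (is.null(k) && k_max < 2L) stop("k_max must be >= 2")
  if (!is.null(k) && k < 1L) stop("k must be >= 1")
  stopifnot(restarts >= 1L, span > 0, span <= 1, alpha > 0, alpha < 1)
  structure(list(input = input, covariates_csv = covariates_csv,
                 simulate = isTRUE(simulate),
                 feature_kind = feature_kind, k = k, k_max = as.integer(k_max),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 span = span, alpha = alpha, out_dir = out_dir,
                 write_features = isTRUE(write_features)),
            class = "run_config")
}

#' Run the whole analysis pipeline
#'
#' Chains the stages: read or simulate the cohort, apply the wear-validity
#' filter, build the requested feature representation(s), cluster with Lloyd
#' k-means (elbow-selected k unless fixed), name the clusters from their
#' smoothed diel curves, quantify MVPA bouts, compare covariates across
#' clusters, and write every artifact plus a machine-readable run manifest.
#' Identical config and seed yield identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results (`cohort`,
#'   `exclusions`, per-kind `fits`, `curves`, `names`, `bouts`,
#'   `comparisons`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (config$simulate) {
    gen <- generate_cohort(default_trial_config(seed = config$seed))
    cohort <- gen$cohort
    planted <- gen$labels
  } else {
    covs <- if (!is.null(config$covariates_csv)) {
      utils::read.csv(config$covariates_csv, stringsAsFactors = FALSE)
    } else NULL
    cohort <- read_cohort(config$input, "long_csv", covariates = covs)
    planted <- NULL
  }

  filt <- filter_valid_participants(cohort)
  write.csv(filt$exclusions, file.path(config$out_dir, "exclusions.csv"),
            row.names = FALSE)
  cohort <- filt$cohort

  kinds <- switch(config$feature_kind, both = c("raw", "normalized"),
                  config$feature_kind)
  bouts <- bout_summary(cohort)
  write.csv(bouts, file.path(config$out_dir, "bout_summary.csv"), row.names = FALSE)

  specs <- infer_comparison_specs(cohort)
  out <- list(cohort = cohort, exclusions = filt$exclusions, planted = planted,
              bouts = bouts, kinds = list())
  for (kind in kinds) {
    out$kinds[[kind]] <- run_one_kind(cohort, kind, config, bouts, specs)
  }

  manifest <- list(
    config = unclass(config), n_input = length(filt$exclusions$participant_id) +
      length(cohort$traces),
    n_analyzed = length(cohort$traces),
    chosen_k = lapply(out$kinds, function(z) z$fit$k),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("actipatterns")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  out$manifest <- manifest
  invisible(out)
}

run_one_kind <- function(cohort, kind, config, bouts, specs) {
  if (kind == "raw") {
    features <- raw_feature_matrix(cohort)
    fkind <- "raw"
  } else {
    nf <- normalized_feature_matrix(cohort)
    features <- nf$features
    fkind <- "normalized_mvpa"
    if (length(nf$degenerate_ids)) {
      bouts <- bouts[bouts$participant_id %in% rownames(features), , drop = FALSE]
    }
  }
  tag <- function(name) file.path(config$out_dir, paste0(name, "_", kind, ".csv"))
  if (config$write_features) write_feature_matrix(features, tag("features"))

  if (is.null(config$k)) {
    scan <- elbow_scan(features, config$k_max, restarts = config$restarts,
                       seed = config$seed)
    write.csv(data.frame(k = scan$k_values, wss = scan$wss_by_k,
                         chosen = scan$k_values == scan$chosen_k),
              tag("elbow_scan"), row.names = FALSE)
    fit <- scan$fits[[scan$chosen_k]]
  } else {
    scan <- NULL
    fit <- lloyd_kmeans(features, config$k, restarts = config$restarts,
                        seed = config$seed)
  }

  curves <- smoothed_curves(features, fit$labels, span = config$span)
  names_map <- if (fit$k >= 2L) name_clusters(fit, curves, fkind) else
    stats::setNames("all", "1")
  write.csv(data.frame(participant_id = names(fit$labels),
                       cluster = unname(fit$labels),
                       name = names_map[as.character(fit$labels)]),
            tag("labels"), row.names = FALSE)
  write.csv(curves_table(curves), tag("curves"), row.names = FALSE)

  comparison <- NULL
  if (fit$k >= 2L && nrow(specs) > 0L) {
    comparison <- compare_groups(cohort_subset(cohort, names(fit$labels)),
                                 fit$labels, specs, alpha = config$alpha)
    tab <- cluster_summary_table(comparison, fit$labels,
                                 cluster_names = names_map, bouts = bouts)
    write.csv(tab, tag("comparison"), row.names = FALSE)
  }
  list(features_kind = fkind, fit = fit, scan = scan, curves = curves,
       names = names_map, comparison = comparison)
}

cohort_subset <- function(cohort, ids) {
  cohort_dataset(cohort$traces[intersect(names(cohort$traces), ids)],
                 cohort$covariates[cohort$covariates$participant_id %in% ids, ,
                                   drop = FALSE])
}

# every non-id covariate column becomes a comparison: numeric -> continuous
infer_comparison_specs <- function(cohort) {
  vars <- setdiff(names(cohort$covariates), "participant_id")
  if (length(vars) == 0L) {
    return(data.frame(variable = character(), type = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(vars, function(v) {
    comparison_spec(v, if (is.numeric(cohort$covariates[[v]])) "continuous"
                    else "categorical")
  }))
}
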