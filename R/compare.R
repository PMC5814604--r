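#' Comparison specification
#'
#' Declares how one covariate is compared across clusters: a one-way ANOVA
#' F-test for continuous variables, a Pearson chi-square test on the
#' cluster-by-level contingency table for categorical ones.
#'
#' @param variable Covariate column name.
#' @param type `"continuous"` or `"categorical"`.
#' @return A one-row data frame; rbind several to form a spec table.
#' @export
comparison_spec <- function(variable, type = c("continuous", "categorical")) {
  type <- match.arg(type)
  data.frame(variable = variable, type = type, stringsAsFactors = FALSE)
}

# overall test on one variable; returns list(statistic, df, p, note)
overall_test <- function(values, groups, type) {
  if (type == "continuous") {
    g <- factor(groups)
    ok <- !is.na(values)
    v <- values[ok]; g <- droplevels(g[ok])
    if (nlevels(g) < 2L) return(list(statistic = NA_real_, df = NA, p = NA_real_,
                                     note = "fewer than 2 groups with data"))
    if (all(tapply(v, g, function(z) length(unique(z)) <= 1L))) {
      return(list(statistic = NA_real_, df = NA, p = NA_real_,
                  note = "zero within-group variance"))
    }
    a <- stats::anova(stats::lm(v ~ g))
    list(statistic = a[["F value"]][1], df = c(a$Df[1], a$Df[2]),
         p = a[["Pr(>F)"]][1], note = NA_character_)
  } else {
    tab <- table(groups, values)
    zero_lvl <- colSums(tab) == 0
    if (any(zero_lvl)) {
      warning("dropping all-zero level(s): ",
              paste(colnames(tab)[zero_lvl], collapse = ", "))
      tab <- tab[, !zero_lvl, drop = FALSE]
    }
    if (ncol(tab) < 2L) return(list(statistic = NA_real_, df = NA, p = NA_real_,
                                    note = "fewer than 2 observed levels"))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value, note = NA_character_)
  }
}

pairwise_tests <- function(values, groups, type, t_variant, adjust) {
  g <- factor(groups)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    sel <- g %in% pr
    if (type == "continuous") {
      p <- tryCatch(
        stats::t.test(values[sel] ~ droplevels(g[sel]),
                      var.equal = (t_variant == "pooled"))$p.value,
        error = function(e) NA_real_)
    } else {
      tab <- table(droplevels(g[sel]), values[sel])
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      p <- if (ncol(tab) < 2L) NA_real_ else
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    data.frame(group_a = pr[1], group_b = pr[2], p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Compare covariates across clusters
#'
#' For each declared covariate, runs the overall test across all clusters;
#' pairwise follow-up tests (two-sample t-tests for continuous variables,
#' 2-group chi-squares for categorical ones) are performed only when the
#' overall p-value is below `alpha`. Pairwise p-values are unadjusted by
#' default, matching common reporting practice; Holm adjustment is available.
#'
#' @param cohort A `cohort_dataset` whose covariate table holds the variables.
#' @param labels Named integer cluster labels (names = participant ids).
#' @param specs Spec table from [comparison_spec()] rows.
#' @param alpha Significance level gating pairwise follow-ups, default 0.05.
#' @param t_variant `"welch"` (default, unequal variances) or `"pooled"` for
#'   pairwise t-tests.
#' @param adjust Multiplicity adjustment for pairwise p-values: `"none"`
#'   (default) or any [stats::p.adjust()] method such as `"holm"`.
#' @return A list of per-variable results (class `group_comparison`), each
#'   with `variable`, `type`, `statistic`, `df`, `p`, `note`, `by_cluster`
#'   summaries, and `pairwise` (empty data frame when the overall test is not
#'   significant).
#' @export
compare_groups <- function(cohort, labels, specs, alpha = 0.05,
                           t_variant = c("welch", "pooled"), adjust = "none") {
  t_variant <- match.arg(t_variant)
  stopifnot(inherits(cohort, "cohort_dataset"), is.data.frame(specs),
            all(c("variable", "type") %in% names(specs)))
  cov <- cohort$covariates
  ids <- names(labels)
  stopifnot(!is.null(ids), all(ids %in% cov$participant_id))
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters to compare")
  cov <- cov[match(ids, cov$participant_id), , drop = FALSE]

  results <- lapply(seq_len(nrow(specs)), function(i) {
    var <- specs$variable[i]; type <- specs$type[i]
    if (!var %in% names(cov)) stop("covariate not found: ", var)
    values <- cov[[var]]
    if (type == "continuous" && !is.numeric(values)) {
      stop("covariate ", var, " declared continuous but is not numeric")
    }
    ov <- overall_test(values, labels, type)
    by_cluster <- summarize_by_cluster(values, labels, type)
    pw <- if (!is.na(ov$p) && ov$p < alpha) {
      pairwise_tests(values, labels, type, t_variant, adjust)
    } else {
      data.frame(group_a = character(), group_b = character(),
                 p = numeric(), p_adjusted = numeric(), stringsAsFactors = FALSE)
    }
    list(variable = var, type = type, statistic = ov$statistic, df = ov$df,
         p = ov$p, note = ov$note, by_cluster = by_cluster, pairwise = pw)
  })
  structure(results, class = "group_comparison", alpha = alpha)
}

summarize_by_cluster <- function(values, labels, type) {
  cl <- sort(unique(labels))
  if (type == "continuous") {
    do.call(rbind, lapply(cl, function(j) {
      v <- values[labels == j]
      data.frame(cluster = j, n = sum(!is.na(v)),
                 mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
    }))
  } else {
    tab <- table(labels, values)
    as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  }
}

#' Formatted cluster comparison table
#'
#' Renders the comparison in the familiar baseline-table shape: one column
#' per cluster headed `name (n=...)`, cells `mean (SD)` for continuous
#' variables and `n (%)` per level for categorical ones, an overall p-value
#' column, and the significant pairwise contrasts.
#'
#' @param comparison A `group_comparison` from [compare_groups()].
#' @param labels The cluster labels used for the comparison.
#' @param cluster_names Optional named character vector (from
#'   [name_clusters()]) used in column headers.
#' @param bouts Optional [bout_summary()] data frame; when given, the weekly
#'   MVPA and steps rows are appended with per-cluster mean (SD).
#' @return A character data frame ready for CSV or Markdown export.
#' @export
cluster_summary_table <- function(comparison, labels, cluster_names = NULL,
                                  bouts = NULL) {
  stopifnot(inherits(comparison, "group_comparison"))
  cl <- sort(unique(labels))
  sizes <- table(labels)[as.character(cl)]
  heads <- vapply(seq_along(cl), function(i) {
    nm <- if (!is.null(cluster_names)) cluster_names[[as.character(cl[i])]] else
      paste0("cluster_", cl[i])
    sprintf("%s (n=%d)", nm, sizes[i])
  }, character(1))

  fmt_cont <- function(bc, j) sprintf("%.1f (%.1f)", bc$mean[bc$cluster == j],
                                      bc$sd[bc$cluster == j])
  rows <- list()
  for (res in comparison) {
    if (res$type == "continuous") {
      cells <- vapply(cl, function(j) fmt_cont(res$by_cluster, j), character(1))
      rows[[length(rows) + 1L]] <- c(res$variable, cells, fmt_p(res$p),
                                     fmt_pairwise(res$pairwise))
    } else {
      lv <- unique(res$by_cluster$values)
      for (l in lv) {
        cells <- vapply(cl, function(j) {
          n <- res$by_cluster$n[res$by_cluster$labels == j & res$by_cluster$values == l]
          sprintf("%d (%.1f%%)", n, 100 * n / sizes[as.character(j)])
        }, character(1))
        first <- l == lv[1]
        rows[[length(rows) + 1L]] <- c(paste0(res$variable, ": ", l), cells,
                                       if (first) fmt_p(res$p) else "",
                                       if (first) fmt_pairwise(res$pairwise) else "")
      }
    }
  }
  if (!is.null(bouts)) {
    for (var in intersect(c("weekly_mvpa_1min", "weekly_mvpa_5min",
                            "weekly_mvpa_10min", "mean_daily_steps"),
                          names(bouts))) {
      cells <- vapply(cl, function(j) {
        v <- bouts[[var]][labels[match(bouts$participant_id, names(labels))] == j]
        sprintf("%.1f (%.1f)", mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE))
      }, character(1))
      rows[[length(rows) + 1L]] <- c(var, cells, "", "")
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("variable", heads, "overall_p", "significant_pairwise")
  out
}

fmt_p <- function(p) {
  if (is.na(p)) "NA" else if (p < 0.001) "<.001" else sub("^0", "", sprintf("%.3f", p))
}

fmt_pairwise <- function(pw) {
  if (nrow(pw) == 0L) return("")
  paste(sprintf("%s vs %s: %s", pw$group_a, pw$group_b,
                vapply(pw$p, fmt_p, character(1))), collapse = "; ")
}
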