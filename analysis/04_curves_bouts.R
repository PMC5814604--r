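#!/usr/bin/env Rscript
# Stage 4: smoothed diel curves, cluster naming, and MVPA bouts.
#
# Computes each cluster's mean minute-of-day activity curve, loess-smooths it
# (span 0.1), names clusters from the curve shapes, and quantifies weekly
# MVPA under the 1-, 5- and 10-minute bout criteria plus mean daily steps.

suppressPackageStartupMessages(library(actipatterns))

covs <- read.csv("scratch/covariates_valid.csv", stringsAsFactors = FALSE)
cohort <- read_cohort("scratch/cohort_valid.csv", "long_csv", covariates = covs)

bouts <- bout_summary(cohort)
write.csv(bouts, "scratch/bout_summary.csv", row.names = FALSE)

for (kind in c("raw", "normalized")) {
  lab_df <- read.csv(sprintf("results/labels_%s.csv", kind),
                     stringsAsFactors = FALSE)
  labels <- stats::setNames(lab_df$cluster, lab_df$participant_id)
  feats <- if (kind == "raw") raw_feature_matrix(cohort) else
    normalized_feature_matrix(cohort)$features
  labels <- labels[rownames(feats)]
  curves <- smoothed_curves(feats, labels, span = 0.1)
  fkind <- if (kind == "raw") "raw" else "normalized_mvpa"
  fit <- structure(list(k = max(labels)), class = "lloyd_kmeans")
  nm <- name_clusters(fit, curves, fkind)
  cat(sprintf("[%s] cluster names: %s\n", kind,
              paste(sprintf("%s=%s", names(nm), nm), collapse = ", ")))
  write.csv(transform(lab_df, name = nm[as.character(lab_df$cluster)]),
            sprintf("results/labels_named_%s.csv", kind), row.names = FALSE)
  tab <- curves_table(curves)
  tab$raw_mean <- signif(tab$raw_mean, 6)
  tab$smoothed <- signif(tab$smoothed, 6)
  write.csv(tab, sprintf("scratch/curves_%s.csv", kind), row.names = FALSE)

  mvpa <- tapply(bouts$weekly_mvpa_1min, nm[as.character(labels[bouts$participant_id])],
                 mean)
  cat(sprintf("[%s] mean weekly MVPA minutes (1-min criterion) by cluster:\n", kind))
  print(round(mvpa, 1))
}
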