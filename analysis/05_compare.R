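#!/usr/bin/env Rscript
# Stage 5: covariate comparison across clusters.
#
# Chi-square (categorical) / one-way ANOVA (continuous) across the raw-MET
# clusters, with pairwise follow-ups only where the overall test is
# significant, rendered as the familiar baseline-comparison table.

suppressPackageStartupMessages(library(actipatterns))

covs <- read.csv("scratch/covariates_valid.csv", stringsAsFactors = FALSE)
cohort <- read_cohort("scratch/cohort_valid.csv", "long_csv", covariates = covs)
bouts <- read.csv("scratch/bout_summary.csv", stringsAsFactors = FALSE)

for (kind in c("raw", "normalized")) {
  lab_df <- read.csv(sprintf("results/labels_named_%s.csv", kind),
                     stringsAsFactors = FALSE)
  labels <- stats::setNames(lab_df$cluster, lab_df$participant_id)
  nm <- stats::setNames(lab_df$name, lab_df$cluster)
  nm <- nm[!duplicated(names(nm))]
  specs <- rbind(comparison_spec("age", "continuous"),
                 comparison_spec("cesd", "continuous"),
                 comparison_spec("bmi", "continuous"),
                 comparison_spec("education", "categorical"))
  sub <- cohort
  if (!all(names(cohort$traces) %in% names(labels))) {
    keep <- intersect(names(cohort$traces), names(labels))
    sub <- cohort_dataset(cohort$traces[keep],
                          cohort$covariates[cohort$covariates$participant_id %in% keep, ])
  }
  res <- compare_groups(sub, labels, specs)
  tab <- cluster_summary_table(res, labels, cluster_names = nm, bouts = bouts)
  write.csv(tab, sprintf("results/comparison_%s.csv", kind), row.names = FALSE)
  cat(sprintf("\n[%s] cluster comparison:\n", kind))
  print(tab, row.names = FALSE)
}
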