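#!/usr/bin/env Rscript
# Stage 3: feature construction and k-means clustering.
#
# Builds both feature representations from the validity-filtered cohort —
# raw 10,080-minute MET vectors (missing minutes imputed to 1 MET) and
# unit-normalized 1440-minute MVPA-frequency profiles — then runs Lloyd
# k-means with 25 random restarts over k = 1..5 and selects k by the elbow
# rule. Labels and the elbow scans land in results/.

suppressPackageStartupMessages(library(actipatterns))

seed <- 20260925L
covs <- read.csv("scratch/covariates_valid.csv", stringsAsFactors = FALSE)
cohort <- read_cohort("scratch/cohort_valid.csv", "long_csv", covariates = covs)

raw <- raw_feature_matrix(cohort)
norm <- normalized_feature_matrix(cohort)
cat(sprintf("features: raw %d x %d, normalized %d x %d (%d degenerate)\n",
            nrow(raw), ncol(raw), nrow(norm$features), ncol(norm$features),
            length(norm$degenerate_ids)))

for (kind in c("raw", "normalized")) {
  feats <- if (kind == "raw") raw else norm$features
  scan <- elbow_scan(feats, k_max = 5L, restarts = 25L, seed = seed)
  cat(sprintf("[%s] WSS by k: %s -> chosen k = %d\n", kind,
              paste(signif(scan$wss_by_k, 4), collapse = ", "), scan$chosen_k))
  write.csv(data.frame(k = scan$k_values, wss = scan$wss_by_k,
                       chosen = scan$k_values == scan$chosen_k),
            sprintf("results/elbow_%s.csv", kind), row.names = FALSE)
  fit <- scan$fits[[scan$chosen_k]]
  cat(sprintf("[%s] cluster sizes: %s; variance explained %.1f%%\n", kind,
              paste(tabulate(fit$labels, fit$k), collapse = "/"),
              100 * fit$variance_explained))
  write.csv(data.frame(participant_id = names(fit$labels),
                       cluster = unname(fit$labels)),
            sprintf("results/labels_%s.csv", kind), row.names = FALSE)
}
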