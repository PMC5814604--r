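#!/usr/bin/env Rscript
# Stage 2: wear-validity filtering.
#
# Reads the minute-level cohort written by 01_simulate.R and applies the
# 7-days-at->=8h wear rule. Participants who never wore the device (run-in
# failures) have no observed minutes, hence no rows in the long CSV at all:
# they drop out at ingestion, and the covariate table is the record of their
# enrollment. The wear filter then removes the insufficient-wear group.

suppressPackageStartupMessages(library(actipatterns))

covs <- read.csv("scratch/covariates.csv", stringsAsFactors = FALSE)
cohort <- suppressWarnings(
  read_cohort("scratch/cohort_long.csv", "long_csv", covariates = covs))
n_enrolled <- nrow(covs)
n_recorded <- length(cohort$traces)
cat(sprintf("enrolled %d; %d with recorded wear, %d run-in failures (no data rows)\n",
            n_enrolled, n_recorded, n_enrolled - n_recorded))

filt <- filter_valid_participants(cohort)
write.csv(filt$exclusions, "results/exclusions.csv", row.names = FALSE)
cat(sprintf("validity filter: %d retained, %d excluded for insufficient wear\n",
            length(filt$cohort$traces), nrow(filt$exclusions)))

# survivors only, for downstream stages
write_cohort_long(filt$cohort, "scratch/cohort_valid.csv")
write.csv(filt$cohort$covariates, "scratch/covariates_valid.csv", row.names = FALSE)
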