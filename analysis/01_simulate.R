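#!/usr/bin/env Rscript
# Stage 1: simulate the two study cohorts.
#
# The reproducibility cohort (7 patients, 7 primaries + ~11 nodes) carries
# duplicate baseline scans; the response cohort (12 patients, 12 primaries
# + ~18 nodes) additionally carries an on-treatment scan generated under
# the published response-model effects. Per-patient RT schedules are drawn
# over the study's 5-11 delivered fractions.

suppressPackageStartupMessages(library(fltrt))
dir.create("results", showWarnings = FALSE)
seed <- 20260929L

repro <- generate_cohort(cohort_config_reproducibility(seed = seed))
resp <- generate_cohort(cohort_config_response(seed = seed + 1L))

set.seed(seed + 2L)
pats <- unique(resp$patient_id)
schedules <- data.frame(
  patient_id = pats,
  n_fractions_at_scan3 = sample(5:11, length(pats), replace = TRUE),
  dose_per_fraction_Gy = 2.75)

write_cohort_csv(repro, "results/cohort_reproducibility.csv")
write_cohort_csv(resp, "results/cohort_response.csv")
write.csv(schedules, "results/rt_schedules.csv", row.names = FALSE)

cat(sprintf("reproducibility cohort: %d patients, %d lesions (%d nodes)\n",
            length(unique(repro$patient_id)),
            length(unique(repro$lesion_id)),
            sum(repro$lesion_type == "node" & repro$scan_label == "S1")))
cat(sprintf("response cohort: %d patients, %d lesions (%d nodes)\n",
            length(unique(resp$patient_id)),
            length(unique(resp$lesion_id)),
            sum(resp$lesion_type == "node" & resp$scan_label == "S1")))
cat("wrote results/cohort_reproducibility.csv, cohort_response.csv,",
    "rt_schedules.csv\n")
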