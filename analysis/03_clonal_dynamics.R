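#!/usr/bin/env Rscript
# Differential-abundance analysis of tumor subclusters within each
# longitudinal pair: permutation test (B = 10,000) on cluster compositions,
# classification at FDR < 0.05 and |log2 fold-difference| >= 1, compared
# against the planted truth.
#
# Run from the repository root: Rscript analysis/03_clonal_dynamics.R

source("analysis/00_config.R")

cohort <- generate_cohort(ref_config())
cells <- cohort$cells

rows <- list()
for (p in sort(unique(cells$patient_id))) {
  idx <- cells$patient_id == p
  res <- proportion_shift_test(cells$timepoint[idx], cells$cluster[idx],
                               B = 10000, seed = derive_seed(REF_SEED, paste0("dyn_", p)))
  res <- classify_clusters(res)
  rows[[p]] <- cbind(patient_id = p, res)
  message(sprintf("%s: %s expanding, %s shrinking", p,
                  paste(res$cluster[res$class == "expanding"], collapse = ","),
                  paste(res$cluster[res$class == "shrinking"], collapse = ",")))
}
dyn <- do.call(rbind, rows)
write_result(dyn, "clonal_dynamics.tsv")

truth <- rbind(cbind(cohort$truth$expanding_clusters, class = "expanding"),
               cbind(cohort$truth$shrinking_clusters, class = "shrinking"))
called <- dyn[dyn$class != "stable", c("patient_id", "cluster", "class")]
called$cluster <- as.integer(called$cluster)
hit <- merge(truth, called,
             by.x = c("patient_id", "cluster", "class"),
             by.y = c("patient_id", "cluster", "class"))
message(sprintf("recovered %d / %d planted shifts; %d false calls",
                nrow(hit), nrow(truth), nrow(called) - nrow(hit)))
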