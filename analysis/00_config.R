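# Shared settings for the analysis workflow.
#
# The reference cohort is fully determined by REF_SEED: every numbered script
# regenerates it with `generate_cohort(sim_config(seed = REF_SEED))` instead
# of reading a serialized count matrix, so the workflow stays text-only and
# each script is independently runnable.

library(tpllprog)

REF_SEED <- 1L
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

ref_config <- function() sim_config(seed = REF_SEED)

write_result <- function(df, name) {
  path <- file.path(RESULTS, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
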