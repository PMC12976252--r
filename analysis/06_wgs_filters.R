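#!/usr/bin/env Rscript
# Somatic short-variant retention filtering (VAF >= 5%, depth >= 10, >= 3 alt
# reads, population AF <= 0.01, dbSNP/TOPMed MAF <= 0.05) and longitudinal
# VAF trajectories per gene, on the variants injected for the reference
# cohort (reads the VCFs written by 01_simulate.R).
#
# Run from the repository root: Rscript analysis/06_wgs_filters.R

source("analysis/00_config.R")

vcf_i <- file.path(RESULTS, "variants_indolent.vcf")
if (!file.exists(vcf_i)) {
  message("variant VCFs not found under results/; run analysis/01_simulate.R first")
  quit(status = 1)
}
vi <- read_variants(vcf_i)
va <- read_variants(file.path(RESULTS, "variants_active.vcf"))

fi <- filter_short_variants(vi)
fa <- filter_short_variants(va)
message(sprintf("retention: %d/%d indolent and %d/%d active variants pass",
                sum(fi$verdict == "pass"), nrow(fi),
                sum(fa$verdict == "pass"), nrow(fa)))
write_result(fi, "variants_indolent_verdicts.tsv")
write_result(fa, "variants_active_verdicts.tsv")

genes <- unique(na.omit(c(fi$gene, fa$gene)))
traj <- vaf_trajectory(fi, fa, genes)
write_result(traj, "vaf_trajectory.tsv")
for (i in seq_len(nrow(traj))) {
  message(sprintf("%s: mean VAF %.1f%% -> %.1f%% (delta %+.1f points)",
                  traj$gene[i], 100 * traj$mean_vaf_indolent[i],
                  100 * traj$mean_vaf_active[i], 100 * traj$delta[i]))
}
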