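#!/usr/bin/env Rscript
# Simulate the reference paired cohort (4 patients, indolent + active sample
# each, 3000 cells per sample, 5000 genes) with planted cluster dynamics,
# DEGs, a subclone-specific expression program, and longitudinal somatic
# variants. Writes the planted ground truth and cohort summaries.
#
# Run from the repository root: Rscript analysis/01_simulate.R

source("analysis/00_config.R")

cfg <- ref_config()
cohort <- generate_cohort(cfg)
variants <- inject_variants(cfg)

message(sprintf("cohort: %d cells x %d genes over %d patients",
                n_cells(cohort$counts), n_genes(cohort$counts),
                cfg$n_patients))
message(sprintf("planted: %d expanding and %d shrinking clusters, %d recurrent + %d private DEGs per patient",
                nrow(cohort$truth$expanding_clusters),
                nrow(cohort$truth$shrinking_clusters),
                cfg$n_recurrent_degs, cfg$n_private_degs))

write_result(cohort$truth$cluster_props, "truth_cluster_props.tsv")
write_result(cohort$truth$deg_table, "truth_degs.tsv")
write_result(head(cohort$cells, 50), "cells_preview.tsv")
write_variants_vcf(variants$indolent, file.path(RESULTS, "variants_indolent.vcf"))
write_variants_vcf(variants$active, file.path(RESULTS, "variants_active.vcf"))
message("done; downstream scripts regenerate the counts from REF_SEED")
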