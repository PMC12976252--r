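#!/usr/bin/env Rscript
# Quality filtering and normalization of the reference cohort: keep cells
# with 250-4500 detected features and < 20% mitochondrial counts, then
# library-size normalize (scale 1e4) with log1p.
#
# Run from the repository root: Rscript analysis/02_preprocess.R

source("analysis/00_config.R")

cohort <- generate_cohort(ref_config())
qc <- qc_filter(cohort$counts, cohort$annotation)
rep <- qc$report

message(sprintf("QC kept %d of %d cells (%.2f%%)",
                attr(rep, "n_cells_kept"), attr(rep, "n_cells_in"),
                100 * attr(rep, "n_cells_kept") / attr(rep, "n_cells_in")))
removed <- rep[!rep$kept, ]
if (nrow(removed)) {
  message("removal reasons: ",
          paste(names(table(removed$reasons)), table(removed$reasons),
                sep = "=", collapse = ", "))
}

norm <- normalize_log1p(qc$counts)
message(sprintf("normalized matrix: %d cells x %d genes, %.1f%% non-zero",
                n_cells(norm), n_genes(norm),
                100 * length(norm$values@x) / prod(dim(norm$values))))

qc_summary <- data.frame(
  n_cells_in = attr(rep, "n_cells_in"),
  n_cells_kept = attr(rep, "n_cells_kept"),
  median_features = median(rep$n_features),
  median_pct_mito = median(rep$pct_mito)
)
write_result(qc_summary, "qc_summary.tsv")
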