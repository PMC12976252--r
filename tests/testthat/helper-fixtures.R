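# Shared fixture builders. Everything is generated in code; no binary data.

# small Poisson count matrix with optional all-zero guard
make_counts <- function(n_cells = 50, n_genes = 30, lambda = 2, seed = 1) {
  set.seed(seed)
  v <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes)
  v[rowSums(v) == 0, 1] <- 1L                  # no zero-total cells
  count_matrix(v, sprintf("g%03d", seq_len(n_genes)),
               sprintf("c%03d", seq_len(n_cells)))
}

# tiny cohort for pipeline-level tests
small_cohort <- function(seed = 7) {
  cfg <- sim_config(
    n_patients = 2, cells_per_sample = 400, n_genes = 600,
    n_recurrent_degs = 10, n_private_degs = 5,
    signature_sets = list(SIG = list(n_genes = 20, multiplier = 4)),
    seed = seed
  )
  list(cfg = cfg, cohort = generate_cohort(cfg))
}

# annotation where all genes are coding and none mitochondrial/metabolic
plain_annotation <- function(gene_ids) {
  data.frame(gene_id = gene_ids, is_protein_coding = TRUE,
             is_metabolic = FALSE, is_mitochondrial = FALSE)
}

extdata <- function(name) {
  system.file("extdata", name, package = "tpllprog", mustWork = TRUE)
}
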