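#' Default stage parameters for the progression pipeline
#'
#' Mirrors the stage defaults: QC bounds (250-4500 features, <20%
#' mitochondrial), log1p normalization scaled by 1e4, 15 principal
#' components, SNN at resolution 5 for the pairwise tumor analysis,
#' differential-abundance gates FDR < 0.05 and |log2FD| >= 1 at B = 10,000,
#' DEG gates adjusted p < 0.05 and |log2FC| >= 0.5 with a 1%-expressed
#' filter, recurrence threshold k = 2, module-score bins/controls 24/100,
#' and the somatic-variant retention thresholds of [filter_config()].
#'
#' @param ... overrides for individual entries.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    min_features = 250, max_features = 4500, max_mito = 0.20,
    scale_factor = 1e4,
    n_components = 15, n_hvg = 2000,
    k_neighbors = 20, resolution_pair = 5, snn_prune = 1 / 15,
    cluster_source = "metadata",      # "metadata" or "snn"
    dynamics_B = 10000, alpha = 0.05, tau = 1.0,
    de_min_frac = 0.01, p_adj_cutoff = 0.05, lfc_cutoff = 0.5,
    recurrence_B = 10000, recurrence_k = 2,
    score_n_bins = 24, score_n_ctrl = 100, score_B = 10000,
    wgs_filter = filter_config()
  )
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

#' Run the full progression analysis pipeline on a cohort
#'
#' Stage order: QC -> normalization -> per-pair cluster labels -> per-pair
#' differential-abundance permutation test -> per-pair Wilcoxon differential
#' expression -> cross-patient DEG recurrence test -> pseudobulk
#' negative-binomial LRT (paired, active vs indolent) -> gene-set module
#' scores with the mixed paired/unpaired permutation comparison -> cluster
#' activity scores -> metabolic transcript fraction -> somatic-variant
#' retention filter and VAF trajectories. All stage outputs are written as
#' TSV under `output_dir` together with a machine-readable `report.json`;
#' every file embeds the seed and a config checksum, and the report is
#' byte-identical under identical config and seed.
#'
#' @param cohort list with `counts` (raw `count_matrix`), `cells`,
#'   `annotation`, and optionally `gene_sets` (named list) — as produced by
#'   [generate_cohort()] (whose `truth$signature_genes` is used as gene sets
#'   when none are given) or assembled from [read_counts_triplet()] and
#'   friends.
#' @param variants optional list with variant tables `indolent` and `active`.
#' @param output_dir directory for stage outputs.
#' @param params [pipeline_params()] list.
#' @param seed global seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @return the run report (list), invisibly also written to
#'   `output_dir/report.json`.
#' @export
run_pipeline <- function(cohort, variants = NULL, output_dir,
                         params = pipeline_params(), seed = 1L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  gene_sets <- cohort$gene_sets
  if (is.null(gene_sets) && !is.null(cohort$truth$signature_genes)) {
    gene_sets <- cohort$truth$signature_genes
  }
  cfg_hash <- config_checksum(list(params = params, seed = seed))
  provenance <- sprintf("# seed=%d config_hash=%s", seed, cfg_hash)
  report <- list(seed = seed, config_hash = cfg_hash, stages = list())
  tsv <- function(df, name) {
    path <- file.path(output_dir, name)
    con <- file(path, "w")
    writeLines(provenance, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## QC
  qc <- stage("qc", qc_filter(cohort$counts, cohort$annotation,
                              params$min_features, params$max_features,
                              params$max_mito))
  cells <- cohort$cells[match(qc$counts$cell_ids, cohort$cells$cell_id), ]
  tsv(qc$report, "qc_report.tsv")
  report$stages$qc <- list(n_cells_in = attr(qc$report, "n_cells_in"),
                           n_cells_kept = attr(qc$report, "n_cells_kept"))

  ## normalization
  norm <- stage("normalize", normalize_log1p(qc$counts, params$scale_factor))

  ## per-pair cluster labels
  patients <- sort(unique(cells$patient_id[cells$timepoint %in%
                                             c("indolent", "active")]))
  pair_patients <- patients[vapply(patients, function(p) {
    tps <- unique(cells$timepoint[cells$patient_id == p])
    all(c("indolent", "active") %in% tps)
  }, logical(1))]
  clusters <- rep(NA_integer_, nrow(cells))
  stage("cluster", for (p in pair_patients) {
    idx <- which(cells$patient_id == p)
    if (params$cluster_source == "metadata" && "cluster" %in% names(cells) &&
        !anyNA(cells$cluster[idx])) {
      clusters[idx] <- as.integer(cells$cluster[idx])
    } else {
      emb <- pca_embed(subset_counts(norm, cells = idx),
                       n_components = params$n_components, n_hvg = params$n_hvg)
      clusters[idx] <- snn_cluster(emb, k_neighbors = params$k_neighbors,
                                   resolution = params$resolution_pair,
                                   prune = params$snn_prune,
                                   seed = derive_seed(seed, paste0("snn_", p)))
    }
  })

  ## differential abundance per pair
  dynamics <- list()
  for (p in pair_patients) {
    idx <- which(cells$patient_id == p)
    res <- stage("dynamics",
                 proportion_shift_test(cells$timepoint[idx], clusters[idx],
                                       B = params$dynamics_B,
                                       seed = derive_seed(seed, paste0("dyn_", p))))
    res <- classify_clusters(res, alpha = params$alpha, tau = params$tau)
    res <- cbind(patient_id = p, res)
    dynamics[[p]] <- res
    tsv(res, sprintf("dynamics_%s.tsv", p))
  }
  dyn_all <- do.call(rbind, dynamics)
  report$stages$dynamics <- list(
    n_expanding = sum(dyn_all$class == "expanding"),
    n_shrinking = sum(dyn_all$class == "shrinking"),
    expanding = unname(apply(dyn_all[dyn_all$class == "expanding", , drop = FALSE],
                             1, function(r) paste0(r[["patient_id"]], ":", r[["cluster"]]))),
    shrinking = unname(apply(dyn_all[dyn_all$class == "shrinking", , drop = FALSE],
                             1, function(r) paste0(r[["patient_id"]], ":", r[["cluster"]])))
  )

  ## per-pair Wilcoxon DE (active vs indolent)
  deg_sets <- list(); universes <- list()
  for (p in pair_patients) {
    idx <- which(cells$patient_id == p)
    genes_p <- stage("de", expression_fraction_filter(norm, idx,
                                                      params$de_min_frac))
    ia <- idx[cells$timepoint[idx] == "active"]
    ii <- idx[cells$timepoint[idx] == "indolent"]
    de <- stage("de", wilcoxon_de(norm, ia, ii, genes = genes_p,
                                  p_adj_cutoff = params$p_adj_cutoff,
                                  lfc_cutoff = params$lfc_cutoff))
    deg_sets[[p]] <- de$gene[de$is_deg]
    universes[[p]] <- genes_p
    tsv(de, sprintf("de_%s.tsv", p))
  }
  report$stages$de <- list(n_deg = stats::setNames(lengths(deg_sets),
                                                   names(deg_sets)))

  ## recurrence
  rec <- stage("recurrence",
               recurrence_permutation_test(deg_sets, universes,
                                           B = params$recurrence_B,
                                           seed = derive_seed(seed, "recurrence"),
                                           k = params$recurrence_k))
  recurrent_genes <- names(which(table(unlist(lapply(deg_sets, unique))) >=
                                   params$recurrence_k))
  report$stages$recurrence <- list(observed = rec$observed, p = rec$p,
                                   k = rec$k, B = rec$B,
                                   multiplicity = as.list(stats::setNames(
                                     as.integer(rec$multiplicity),
                                     names(rec$multiplicity))))
  tsv(data.frame(gene = recurrent_genes), "recurrent_degs.tsv")

  ## pseudobulk NB LRT across the cohort (paired by patient)
  pair_cells <- which(cells$patient_id %in% pair_patients)
  pb <- stage("pseudobulk",
              pseudobulk_aggregate(subset_counts(qc$counts, cells = pair_cells),
                                   cells$sample_id[pair_cells]))
  samp <- unique(cells[pair_cells, c("sample_id", "patient_id", "timepoint")])
  samp <- samp[match(rownames(pb$matrix), samp$sample_id), ]
  keep_genes <- stage("pseudobulk",
                      expression_fraction_filter(qc$counts, pair_cells,
                                                 params$de_min_frac))
  pb$matrix <- pb$matrix[, keep_genes, drop = FALSE]
  pbde <- stage("pseudobulk",
                nb_lrt_de(pb, condition = factor(samp$timepoint,
                                                 c("indolent", "active")),
                          patient = samp$patient_id,
                          p_adj_cutoff = params$p_adj_cutoff,
                          lfc_cutoff = params$lfc_cutoff))
  tsv(pbde, "pseudobulk_de.tsv")
  report$stages$pseudobulk <- list(n_deg = sum(pbde$is_deg, na.rm = TRUE),
                                   n_tested = nrow(pbde))

  ## gene-set module scores + mixed permutation comparison
  score_rows <- list(); score_tests <- list()
  if (length(gene_sets)) {
    for (nm in names(gene_sets)) {
      sc <- stage("score", module_score(norm, gene_sets[[nm]],
                                        n_bins = params$score_n_bins,
                                        n_ctrl = params$score_n_ctrl,
                                        seed = derive_seed(seed, paste0("score_", nm))))
      by_sample <- tapply(sc, cells$sample_id, mean)
      samp_all <- unique(cells[, c("sample_id", "patient_id", "timepoint")])
      samp_all <- samp_all[match(names(by_sample), samp_all$sample_id), ]
      tst <- stage("score", sample_mean_permutation_test(
        as.numeric(by_sample), samp_all$patient_id, samp_all$timepoint,
        B = params$score_B, seed = derive_seed(seed, paste0("scoretest_", nm))))
      score_rows[[nm]] <- data.frame(set = nm, sample_id = names(by_sample),
                                     mean_score = as.numeric(by_sample))
      score_tests[[nm]] <- list(statistic = tst$statistic, p = tst$p)
    }
    tsv(do.call(rbind, score_rows), "module_scores_by_sample.tsv")
  }
  report$stages$module_scores <- score_tests

  ## cluster activity scores (global cluster ids patient:cluster)
  ok <- !is.na(clusters)
  glob_cl <- paste0(cells$patient_id, ":", clusters)[ok]
  act <- if (length(gene_sets)) {
    stage("activity", activity_scores(subset_counts(qc$counts, cells = which(ok)),
                                      glob_cl, gene_sets,
                                      scale_factor = params$scale_factor))
  } else NULL
  if (!is.null(act)) {
    tsv(data.frame(cluster = rownames(act), act, check.names = FALSE),
        "activity_scores.tsv")
  }

  ## metabolic fraction per sample
  met <- stage("metabolic",
               metabolic_fraction(qc$counts, cohort$annotation, per = "sample",
                                  sample_id = cells$sample_id))
  tsv(data.frame(sample_id = names(met), metabolic_fraction = as.numeric(met)),
      "metabolic_fraction.tsv")
  report$stages$metabolic <- as.list(stats::setNames(round(as.numeric(met), 6),
                                                     names(met)))

  ## somatic variants
  if (!is.null(variants)) {
    fi <- stage("wgs", filter_short_variants(variants$indolent, params$wgs_filter))
    fa <- stage("wgs", filter_short_variants(variants$active, params$wgs_filter))
    genes <- unique(stats::na.omit(c(fi$gene, fa$gene)))
    traj <- stage("wgs", vaf_trajectory(fi, fa, genes))
    tsv(fi, "variants_indolent_filtered.tsv")
    tsv(fa, "variants_active_filtered.tsv")
    tsv(traj, "vaf_trajectory.tsv")
    report$stages$wgs <- list(
      n_pass_indolent = sum(fi$verdict == "pass"),
      n_pass_active = sum(fa$verdict == "pass"),
      trajectory = lapply(seq_len(nrow(traj)), function(i) as.list(traj[i, ]))
    )
  }

  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}

# deterministic provenance checksum of a config list (FNV-style over the
# serialized bytes)
config_checksum <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- sum((b + 1) * (seq_along(b) %% 97 + 1)) %% 2147483647
  sprintf("%08x", as.integer(h))
}
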