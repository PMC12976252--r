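#' Derive a stage-specific seed from a global seed
#'
#' One global seed deterministically derives per-stage seeds by hashing the
#' stage name, so individual stages are reproducible in isolation. Result is
#' kept below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483587 + 1)
}

#' Configuration for the synthetic paired cohort generator
#'
#' The generator emulates a longitudinal leukemia cohort: per patient one
#' indolent and one active sample, cells allocated to subclonal clusters by a
#' multinomial, negative-binomial UMI counts with log-normal library sizes and
#' log-normal gene baselines shared across patients. Planted effects are
#' multiplicative on the negative-binomial mean, so true log2 fold-changes
#' equal the configured values exactly.
#'
#' Cluster proportions at the active time point are derived from the indolent
#' proportions by moving each planted cluster to exactly
#' `2^log2fd * p_indolent` and rescaling the remaining clusters
#' proportionally, so the planted log2 fold-difference in proportion is exact
#' and the passive shift of unplanted clusters stays well below the
#' classification cutoff of 1.
#'
#' @param n_patients number of longitudinal pairs.
#' @param cells_per_sample cells per sample (each patient has two samples).
#' @param n_genes number of genes.
#' @param n_clusters_per_patient subclonal clusters per patient.
#' @param cluster_props_indolent probability vector (length
#'   `n_clusters_per_patient`, sums to 1) of cluster proportions at the
#'   indolent time point.
#' @param planted_expanding data.frame with columns `cluster` and `log2fd`:
#'   clusters whose active-stage proportion is moved by `2^log2fd` (positive =
#'   expanding, negative = shrinking); applied in every patient.
#' @param cluster_props_active optional explicit active-stage proportions;
#'   derived from `planted_expanding` when NULL.
#' @param n_recurrent_degs genes up-regulated at the active time point in all
#'   patients.
#' @param n_private_degs genes up-regulated in exactly one patient (per
#'   patient).
#' @param deg_log2fc true log2 fold-change of planted DEGs (active vs
#'   indolent).
#' @param signature_sets named list; each element a list with `n_genes` and
#'   `multiplier`: the set's genes get their mean multiplied in planted
#'   expanding clusters (both time points), emulating a subclone-specific
#'   transcriptional program.
#' @param pct_mito_mean expected mitochondrial fraction of counts.
#' @param n_mito_genes number of genes flagged mitochondrial.
#' @param libsize_lognormal c(meanlog, sdlog) of per-cell library size.
#' @param nb_dispersion negative-binomial dispersion (var = mu + phi mu^2).
#' @param frac_metabolic,frac_coding fractions of genes flagged metabolic /
#'   protein-coding (metabolic genes are a subset of coding genes).
#' @param variant_spec data.frame(gene, chrom, pos, ref, alt, vaf_indolent,
#'   vaf_active, depth) for [inject_variants()].
#' @param seed integer seed; all generator randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 4,
                       cells_per_sample = 3000,
                       n_genes = 5000,
                       n_clusters_per_patient = 6,
                       cluster_props_indolent = c(0.10, 0.32, 0.145, 0.145, 0.145, 0.145),
                       planted_expanding = data.frame(cluster = c(1L, 2L),
                                                      log2fd = c(2, -2)),
                       cluster_props_active = NULL,
                       n_recurrent_degs = 30,
                       n_private_degs = 20,
                       deg_log2fc = 2,
                       signature_sets = list(
                         PROGRAM_EXPANDING = list(n_genes = 50, multiplier = 4)
                       ),
                       pct_mito_mean = 0.05,
                       n_mito_genes = 13,
                       libsize_lognormal = c(meanlog = log(1500), sdlog = 0.35),
                       nb_dispersion = 0.4,
                       frac_metabolic = 0.10,
                       frac_coding = 0.80,
                       variant_spec = default_variant_spec(),
                       seed = 1L) {
  K <- n_clusters_per_patient
  stopifnot(n_patients >= 1, cells_per_sample >= 1, n_genes >= 1, K >= 1,
            length(cluster_props_indolent) == K,
            nb_dispersion > 0, pct_mito_mean >= 0, pct_mito_mean < 1,
            frac_metabolic >= 0, frac_coding <= 1, frac_metabolic <= frac_coding)
  if (abs(sum(cluster_props_indolent) - 1) > 1e-9) {
    stop("sim_config: cluster_props_indolent must sum to 1", call. = FALSE)
  }
  if (is.null(cluster_props_active)) {
    cluster_props_active <- cluster_props_indolent
    if (nrow(planted_expanding)) {
      pl <- planted_expanding$cluster
      cluster_props_active[pl] <- cluster_props_indolent[pl] * 2^planted_expanding$log2fd
      rest <- setdiff(seq_len(K), pl)
      spare <- 1 - sum(cluster_props_active[pl])
      if (spare <= 0) stop("sim_config: planted proportions exceed 1", call. = FALSE)
      cluster_props_active[rest] <- cluster_props_indolent[rest] *
        spare / sum(cluster_props_indolent[rest])
    }
  }
  if (abs(sum(cluster_props_active) - 1) > 1e-9) {
    stop("sim_config: cluster_props_active must sum to 1", call. = FALSE)
  }
  n_sig_genes <- sum(vapply(signature_sets, function(s) s$n_genes, numeric(1)))
  n_planted <- n_recurrent_degs + n_private_degs * n_patients + n_sig_genes +
    n_mito_genes
  if (n_planted > n_genes) {
    stop("sim_config: more planted genes than genes available", call. = FALSE)
  }
  structure(list(
    n_patients = n_patients, cells_per_sample = cells_per_sample,
    n_genes = n_genes, n_clusters_per_patient = K,
    cluster_props_indolent = cluster_props_indolent,
    cluster_props_active = cluster_props_active,
    planted_expanding = planted_expanding,
    n_recurrent_degs = n_recurrent_degs, n_private_degs = n_private_degs,
    deg_log2fc = deg_log2fc, signature_sets = signature_sets,
    pct_mito_mean = pct_mito_mean, n_mito_genes = n_mito_genes,
    libsize_lognormal = libsize_lognormal, nb_dispersion = nb_dispersion,
    frac_metabolic = frac_metabolic, frac_coding = frac_coding,
    variant_spec = variant_spec, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default somatic-variant specification for the synthetic cohort
#'
#' Emulates longitudinal clonal outgrowth: mono-allelic ATM lesions whose
#' allele frequency rises from ~0.70 to ~0.91 between time points, alongside
#' subclonal JAK/STAT pathway mutations without consistent outgrowth.
#'
#' @return data.frame consumed by [inject_variants()].
#' @export
default_variant_spec <- function() {
  data.frame(
    gene = c("ATM", "ATM", "ATM", "JAK3", "STAT5B"),
    chrom = c("chr11", "chr11", "chr11", "chr19", "chr17"),
    pos = c(108236000L, 108247000L, 108259000L, 17835000L, 42200000L),
    ref = c("A", "C", "G", "G", "T"),
    alt = c("G", "T", "A", "A", "C"),
    vaf_indolent = c(0.6976, 0.6976, 0.6978, 0.15, 0.12),
    vaf_active = c(0.9133, 0.9133, 0.9133, 0.18, 0.10),
    depth = c(500L, 500L, 500L, 500L, 500L),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic paired two-time-point cohort with planted truth
#'
#' See [sim_config()] for the generative model. Returns raw counts, per-cell
#' metadata (including the true cluster label), a gene annotation table, and
#' the planted ground truth needed to score every downstream stage.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `counts` (raw `count_matrix`), `cells`
#'   (cell table), `annotation` (gene annotation data.frame), `truth` (list:
#'   `expanding_clusters`, `shrinking_clusters`, `deg_table`,
#'   `recurrent_genes`, `signature_genes`, `signature_effect_table`,
#'   `cluster_props`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "generate_cohort"))
  G <- cfg$n_genes
  K <- cfg$n_clusters_per_patient
  gene_ids <- sprintf("G%05d", seq_len(G))
  patients <- sprintf("p%d", seq_len(cfg$n_patients))

  # gene role assignment: disjoint planted groups
  pool <- seq_len(G)
  take <- function(n) {
    idx <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    idx
  }
  pool <- sample(pool)                      # random gene identities
  mito_idx <- take(cfg$n_mito_genes)
  recurrent_idx <- take(cfg$n_recurrent_degs)
  private_idx <- lapply(patients, function(p) take(cfg$n_private_degs))
  names(private_idx) <- patients
  sig_idx <- lapply(cfg$signature_sets, function(s) take(s$n_genes))

  # annotation flags: metabolic subset of coding; mito genes coding as well
  n_coding <- round(cfg$frac_coding * G)
  n_metab <- round(cfg$frac_metabolic * G)
  coding_idx <- sort(unique(c(mito_idx, pool[seq_len(max(0, n_coding - length(mito_idx)))],
                              recurrent_idx, unlist(private_idx), unlist(sig_idx))))
  if (length(coding_idx) < n_coding) {
    extra <- setdiff(seq_len(G), coding_idx)
    coding_idx <- sort(c(coding_idx, extra[seq_len(n_coding - length(coding_idx))]))
  }
  metab_pool <- setdiff(coding_idx, mito_idx)
  metab_idx <- sort(sample(metab_pool, min(n_metab, length(metab_pool))))
  annotation <- data.frame(
    gene_id = gene_ids,
    is_protein_coding = seq_len(G) %in% coding_idx,
    is_metabolic = seq_len(G) %in% metab_idx,
    is_mitochondrial = seq_len(G) %in% mito_idx,
    stringsAsFactors = FALSE
  )

  # baseline relative expression; mitochondrial share fixed at pct_mito_mean
  rel <- stats::rlnorm(G, meanlog = 0, sdlog = 1.2)
  rel_mito <- rel[mito_idx] / sum(rel[mito_idx]) * cfg$pct_mito_mean
  rel[-mito_idx] <- rel[-mito_idx] / sum(rel[-mito_idx]) * (1 - cfg$pct_mito_mean)
  rel[mito_idx] <- rel_mito

  planted <- cfg$planted_expanding
  expanding_cl <- planted$cluster[planted$log2fd > 0]
  shrinking_cl <- planted$cluster[planted$log2fd < 0]

  # per-cluster signature multipliers (expanding clusters carry the program)
  sig_mult <- rep(1, G)
  sig_effect <- list()
  for (nm in names(cfg$signature_sets)) {
    mult <- cfg$signature_sets[[nm]]$multiplier
    sig_effect[[nm]] <- data.frame(set = nm, cluster = rep(expanding_cl,
                                                           each = 1),
                                   multiplier = mult)
  }

  deg_rows <- list()
  blocks <- list()
  meta <- list()
  fc <- 2^cfg$deg_log2fc
  for (p in patients) {
    deg_idx_p <- c(recurrent_idx, private_idx[[p]])
    deg_rows[[p]] <- data.frame(patient_id = p, gene_id = gene_ids[deg_idx_p],
                                true_log2fc = cfg$deg_log2fc,
                                recurrent = deg_idx_p %in% recurrent_idx,
                                stringsAsFactors = FALSE)
    for (tp in c("indolent", "active")) {
      props <- if (tp == "indolent") cfg$cluster_props_indolent else cfg$cluster_props_active
      n <- cfg$cells_per_sample
      cl <- sample.int(K, n, replace = TRUE, prob = props)
      lib <- stats::rlnorm(n, cfg$libsize_lognormal[[1]], cfg$libsize_lognormal[[2]])
      gmean <- rel
      if (tp == "active") gmean[deg_idx_p] <- gmean[deg_idx_p] * fc
      counts <- sample_nb_block(lib, gmean, cl, expanding_cl,
                                cfg$signature_sets, sig_idx, cfg$nb_dispersion)
      sid <- paste0(p, "_", tp)
      blocks[[sid]] <- counts
      meta[[sid]] <- data.frame(
        cell_id = sprintf("%s_c%04d", sid, seq_len(n)),
        patient_id = p, sample_id = sid, timepoint = tp,
        cluster = cl - 1L, stringsAsFactors = FALSE
      )
    }
  }
  cells <- do.call(rbind, meta)
  rownames(cells) <- NULL
  values <- do.call(rbind, blocks)
  m <- count_matrix(values, gene_ids, cells$cell_id, layer = "raw")
  cells$n_features <- Matrix::rowSums(m$values > 0)
  tot <- Matrix::rowSums(m$values)
  mito_tot <- Matrix::rowSums(m$values[, mito_idx, drop = FALSE])
  cells$pct_mito <- ifelse(tot > 0, mito_tot / tot, 0)
  cells <- validate_cell_table(cells)

  truth <- list(
    expanding_clusters = expand_patient_clusters(patients, expanding_cl),
    shrinking_clusters = expand_patient_clusters(patients, shrinking_cl),
    deg_table = do.call(rbind, deg_rows),
    recurrent_genes = gene_ids[recurrent_idx],
    signature_genes = lapply(sig_idx, function(i) gene_ids[i]),
    signature_effect_table = do.call(rbind, sig_effect),
    cluster_props = data.frame(
      cluster = seq_len(K) - 1L,
      prop_indolent = cfg$cluster_props_indolent,
      prop_active = cfg$cluster_props_active,
      true_log2fd = log2(cfg$cluster_props_active / cfg$cluster_props_indolent)
    )
  )
  list(counts = m, cells = cells, annotation = annotation, truth = truth)
}

expand_patient_clusters <- function(patients, clusters) {
  if (!length(clusters)) {
    return(data.frame(patient_id = character(), cluster = integer()))
  }
  data.frame(patient_id = rep(patients, each = length(clusters)),
             cluster = rep(as.integer(clusters) - 1L, times = length(patients)),
             stringsAsFactors = FALSE)
}

# draw one sample's NB counts (cells x genes sparse); 0-based clusters NOT
# used here -- `cl` is 1-based
sample_nb_block <- function(lib, gmean, cl, expanding_cl, signature_sets,
                            sig_idx, phi) {
  n <- length(lib)
  G <- length(gmean)
  vals <- matrix(0, n, G)
  in_exp <- cl %in% expanding_cl
  groups <- split(seq_len(n), in_exp)
  for (key in names(groups)) {
    idx <- groups[[key]]
    gm <- gmean
    if (key == "TRUE") {
      for (nm in names(signature_sets)) {
        gm[sig_idx[[nm]]] <- gm[sig_idx[[nm]]] * signature_sets[[nm]]$multiplier
      }
    }
    mu <- outer(lib[idx], gm)            # cells x genes
    vals[idx, ] <- stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
  }
  Matrix::Matrix(vals, sparse = TRUE)
}

#' Inject somatic variants with configured longitudinal VAFs
#'
#' Draws binomial alt-read counts at the configured depths for each variant at
#' both time points; both tables carry identical loci.
#'
#' @param cfg a [sim_config()] (uses `variant_spec` and `seed`).
#' @return list with variant tables `indolent` and `active`.
#' @export
inject_variants <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  vs <- cfg$variant_spec
  if (any(vs$vaf_indolent < 0 | vs$vaf_indolent > 1 |
          vs$vaf_active < 0 | vs$vaf_active > 1)) {
    stop("inject_variants: vaf outside [0, 1]", call. = FALSE)
  }
  if (any(vs$depth <= 0)) stop("inject_variants: depth must be positive", call. = FALSE)
  set.seed(derive_seed(cfg$seed, "inject_variants"))
  draw <- function(vafs) {
    alt <- stats::rbinom(nrow(vs), size = vs$depth, prob = vafs)
    data.frame(chrom = vs$chrom, pos = vs$pos, ref = vs$ref, alt = vs$alt,
               depth = as.numeric(vs$depth), alt_reads = as.numeric(alt),
               vaf = alt / vs$depth, pop_af = NA_real_, dbsnp_maf = NA_real_,
               topmed_maf = NA_real_, gene = vs$gene, stringsAsFactors = FALSE)
  }
  list(indolent = draw(vs$vaf_indolent), active = draw(vs$vaf_active))
}

#' Write a complete synthetic-cohort fixture directory
#'
#' Emits the triplet count matrix, cell metadata TSV, gene annotation TSV,
#' gene sets GMT, two VCFs, and the ground-truth tables, all as plain text,
#' via the package's own readers/writers.
#'
#' @param cfg a [sim_config()].
#' @param directory output directory.
#' @return invisibly, the cohort list from [generate_cohort()].
#' @export
simulate_cohort_fixtures <- function(cfg, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(cfg)
  write_counts_triplet(cohort$counts, file.path(directory, "counts"))
  utils::write.table(cohort$cells, file.path(directory, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotation, file.path(directory, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_sets(cohort$truth$signature_genes,
                  file.path(directory, "signatures.gmt"))
  vars <- inject_variants(cfg)
  write_variants_vcf(vars$indolent, file.path(directory, "variants_indolent.vcf"))
  write_variants_vcf(vars$active, file.path(directory, "variants_active.vcf"))
  utils::write.table(cohort$truth$deg_table, file.path(directory, "truth_degs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$cluster_props,
                     file.path(directory, "truth_cluster_props.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cohort)
}
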