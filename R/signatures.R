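.datatable.aware <- TRUE

#' Gene-set module score with expression-matched control genes
#'
#' Per cell, the mean normalized expression of the gene-set genes minus the
#' mean over a pooled multiset of control genes. Controls are matched on
#' average expression: all genes are partitioned into `n_bins` equal-frequency
#' bins of their dataset-wide mean expression (ties broken by a tiny seeded
#' jitter on the ranks so the binning is deterministic per seed), and each
#' gene-set gene draws `n_ctrl` control genes without replacement from its own
#' bin. Draws are pooled across gene-set genes with duplicates kept. Scores
#' are intended to be computed on the entire dataset under comparison, not on
#' subsets.
#'
#' @param m normalized-layer `count_matrix`.
#' @param gene_set character vector of gene symbols; absent genes are dropped
#'   with a warning.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes drawn per gene-set gene (default 100; capped at
#'   bin size).
#' @param seed integer seed for binning jitter and control sampling.
#' @return numeric vector of per-cell scores (named by cell id).
#' @export
module_score <- function(m, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "normalized") stop("module_score: expects the normalized layer",
                                    call. = FALSE)
  if (n_bins > n_genes(m)) stop("module_score: n_bins exceeds gene count",
                                call. = FALSE)
  gi <- match(gene_set, m$gene_ids)
  if (anyNA(gi)) {
    warning("module_score: ", sum(is.na(gi)), " gene(s) absent from matrix",
            call. = FALSE)
    gi <- gi[!is.na(gi)]
  }
  if (!length(gi)) stop("module_score: no gene-set genes present", call. = FALSE)
  set.seed(seed)
  avg <- Matrix::colMeans(m$values)
  r <- rank(avg, ties.method = "average")
  r <- r + stats::runif(length(r), -0.3, 0.3)     # seeded tie-break
  bin <- ceiling(rank(r, ties.method = "first") * n_bins / length(r))
  bin_members <- split(seq_along(bin), bin)
  ctrl <- unlist(lapply(gi, function(g) {
    mem <- bin_members[[as.character(bin[g])]]
    mem[sample.int(length(mem), min(n_ctrl, length(mem)))]
  }), use.names = FALSE)
  set_mean <- Matrix::rowSums(m$values[, gi, drop = FALSE]) / length(gi)
  # control multiset: duplicates weight the mean
  ctrl_tab <- table(ctrl)
  ci <- as.integer(names(ctrl_tab))
  w <- as.numeric(ctrl_tab)
  ctrl_mean <- as.numeric(m$values[, ci, drop = FALSE] %*% w) / sum(w)
  score <- set_mean - ctrl_mean
  names(score) <- m$cell_ids
  score
}

#' Percentile-rank cluster activity scores for gene sets
#'
#' Averages raw expression over clusters, log1p-normalizes the per-cluster
#' profile (library-size scaling to `scale_factor`), converts each gene's
#' per-cluster values to percentile ranks `(midrank - 0.5) / K` across the K
#' clusters (mid-ranks for ties), averages the ranks over the member genes of
#' each set, and shifts by -0.5. Scores therefore lie in [-0.5, 0.5], with
#' all-tie genes landing exactly at 0.
#'
#' @param m raw-layer `count_matrix`.
#' @param clusters cluster label per cell (>= 2 distinct values).
#' @param gene_sets named list of character vectors; sets without any gene in
#'   the matrix are dropped with a warning.
#' @param scale_factor normalization constant (default 1e4).
#' @return matrix clusters x gene sets of activity scores.
#' @export
activity_scores <- function(m, clusters, gene_sets, scale_factor = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "raw") stop("activity_scores: expects the raw layer", call. = FALSE)
  f <- factor(clusters)
  K <- nlevels(f)
  if (K < 2) stop("activity_scores: need >= 2 clusters", call. = FALSE)
  ind <- Matrix::sparseMatrix(i = as.integer(f), j = seq_len(n_cells(m)),
                              x = 1 / as.numeric(table(f))[as.integer(f)],
                              dims = c(K, n_cells(m)))
  avg <- as.matrix(ind %*% m$values)            # clusters x genes, mean raw
  tot <- rowSums(avg)
  norm <- log1p(scale_factor * avg / tot)
  pr <- apply(norm, 2, function(v) (rank(v, ties.method = "average") - 0.5) / K)
  rownames(pr) <- levels(f)
  out <- sapply(names(gene_sets), function(nm) {
    gi <- match(gene_sets[[nm]], m$gene_ids)
    gi <- gi[!is.na(gi)]
    if (!length(gi)) return(rep(NA_real_, K))
    rowMeans(pr[, gi, drop = FALSE]) - 0.5
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = K,
                                       dimnames = list(levels(f), names(gene_sets)))
  drop_sets <- colSums(is.na(out)) == K
  if (any(drop_sets)) {
    warning("activity_scores: set(s) without matrix genes dropped: ",
            paste(colnames(out)[drop_sets], collapse = ", "), call. = FALSE)
    out <- out[, !drop_sets, drop = FALSE]
  }
  out
}

#' Metabolic transcript fraction
#'
#' The share of a unit's protein-coding transcripts that belong to
#' metabolism-associated genes: sum of counts over metabolic genes divided by
#' the sum over protein-coding genes. Per-sample values pool counts over the
#' sample's cells (a count-weighted mean of per-cell fractions), not a mean of
#' per-cell ratios. Metabolic genes must be a subset of protein-coding genes;
#' violations are warned about and intersected away.
#'
#' @param m raw-layer `count_matrix`.
#' @param annotation gene annotation with `gene_id`, `is_protein_coding`,
#'   `is_metabolic`.
#' @param per `"cell"` or `"sample"`.
#' @param sample_id per-cell sample labels (required for `per = "sample"`).
#' @return named numeric vector of fractions (NA where a unit has zero
#'   protein-coding counts).
#' @export
metabolic_fraction <- function(m, annotation, per = c("cell", "sample"),
                               sample_id = NULL) {
  per <- match.arg(per)
  stopifnot(inherits(m, "count_matrix"))
  coding <- annotation$gene_id[annotation$is_protein_coding]
  metab <- annotation$gene_id[annotation$is_metabolic]
  stray <- setdiff(metab, coding)
  if (length(stray)) {
    warning("metabolic_fraction: ", length(stray),
            " metabolic gene(s) not protein-coding; intersected", call. = FALSE)
    metab <- intersect(metab, coding)
  }
  ci <- which(m$gene_ids %in% coding)
  mi <- which(m$gene_ids %in% metab)
  met_counts <- Matrix::rowSums(m$values[, mi, drop = FALSE])
  cod_counts <- Matrix::rowSums(m$values[, ci, drop = FALSE])
  if (per == "cell") {
    frac <- ifelse(cod_counts > 0, met_counts / cod_counts, NA_real_)
    names(frac) <- m$cell_ids
    return(frac)
  }
  if (is.null(sample_id)) stop("metabolic_fraction: sample_id required", call. = FALSE)
  met_s <- tapply(met_counts, sample_id, sum)
  cod_s <- tapply(cod_counts, sample_id, sum)
  out <- ifelse(cod_s > 0, met_s / cod_s, NA_real_)
  out[names(met_s)]
}

#' Permutation test on per-sample means for mixed paired/unpaired designs
#'
#' Tests a difference in condition means over samples (active minus
#' indolent). The null respects the design: for patients with both time
#' points the two within-patient labels are swapped with probability 1/2
#' (sign-flip); labels of unpaired samples are permuted globally among the
#' unpaired samples, preserving the unpaired condition counts. Two-sided,
#' add-one p-value.
#'
#' @param values named numeric vector of per-sample summaries (e.g. mean
#'   module scores).
#' @param patient,timepoint per-sample design vectors aligned with `values`;
#'   `timepoint` in \{"indolent", "active"\}.
#' @param B permutations (default 10000).
#' @param seed integer seed.
#' @return list: `statistic` (observed mean difference), `p`, `B`, `seed`.
#' @export
sample_mean_permutation_test <- function(values, patient, timepoint,
                                         B = 10000, seed = 1L) {
  stopifnot(length(values) == length(patient),
            length(values) == length(timepoint))
  timepoint <- as.character(timepoint)
  bad <- setdiff(unique(timepoint), c("indolent", "active"))
  if (length(bad)) stop("sample_mean_permutation_test: unknown timepoint(s)",
                        call. = FALSE)
  tp_num <- ifelse(timepoint == "active", 1, -1)
  pt <- as.character(patient)
  paired_pts <- names(which(vapply(split(timepoint, pt), function(x) {
    length(x) == 2 && all(sort(x) == c("active", "indolent"))
  }, logical(1))))
  is_paired <- pt %in% paired_pts
  unp <- which(!is_paired)
  n_unp_a <- sum(timepoint[unp] == "active")
  n_unp_i <- length(unp) - n_unp_a
  if (!length(paired_pts) && (n_unp_a < 2 || n_unp_i < 2)) {
    stop("sample_mean_permutation_test: no paired patients and fewer than 2 ",
         "unpaired samples per arm", call. = FALSE)
  }
  n_a <- sum(timepoint == "active"); n_i <- sum(timepoint == "indolent")
  if (n_a == 0 || n_i == 0) {
    stop("sample_mean_permutation_test: need samples in both conditions",
         call. = FALSE)
  }
  stat <- function(sign_vec) {
    sum(values[sign_vec == 1]) / sum(sign_vec == 1) -
      sum(values[sign_vec == -1]) / sum(sign_vec == -1)
  }
  obs <- stat(tp_num)
  set.seed(seed)
  pair_idx <- split(seq_along(values)[is_paired], pt[is_paired])
  exceed <- 0L
  for (b in seq_len(B)) {
    s <- tp_num
    if (length(pair_idx)) {
      flips <- stats::runif(length(pair_idx)) < 0.5
      for (j in which(flips)) s[pair_idx[[j]]] <- -s[pair_idx[[j]]]
    }
    if (length(unp) > 1) s[unp] <- s[unp][sample.int(length(unp))]
    if (abs(stat(s)) >= abs(obs) - 1e-12) exceed <- exceed + 1L
  }
  list(statistic = obs, p = (1 + exceed) / (B + 1), B = B, seed = seed)
}

#' Orient and rescale a pseudotime to run indolent -> active
#'
#' Min-max rescales the pseudotime to [0, 1], then flips it (`1 - pt`) if the
#' mean pseudotime of indolent cells exceeds that of active cells, so the
#' trajectory always runs from the indolent toward the active expression
#' state. Orientation is an involution: an already-oriented vector is
#' returned unchanged.
#'
#' @param pt numeric pseudotime per cell.
#' @param timepoint per-cell labels; must contain both "indolent" and
#'   "active".
#' @return numeric vector in [0, 1].
#' @export
orient_pseudotime <- function(pt, timepoint) {
  if (!all(c("indolent", "active") %in% timepoint)) {
    stop("orient_pseudotime: both time points must be present", call. = FALSE)
  }
  rng <- range(pt)
  if (rng[1] == rng[2]) {
    warning("orient_pseudotime: constant pseudotime", call. = FALSE)
    return(rep(0.5, length(pt)))
  }
  x <- (pt - rng[1]) / (rng[2] - rng[1])
  if (mean(x[timepoint == "indolent"]) > mean(x[timepoint == "active"])) {
    x <- 1 - x
  }
  x
}
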