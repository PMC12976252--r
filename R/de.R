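#' Filter genes by expression fraction
#'
#' Keeps genes detected (count > 0) in at least `ceil(min_frac * n_cells)` of
#' the given cells.
#'
#' @param m `count_matrix` (either layer; detection uses non-zero entries).
#' @param cells indices or ids of the cell subset.
#' @param min_frac minimum detection fraction (default 0.01).
#' @return character vector of retained gene ids.
#' @export
expression_fraction_filter <- function(m, cells = seq_len(n_cells(m)),
                                       min_frac = 0.01) {
  stopifnot(inherits(m, "count_matrix"))
  if (length(cells) == 0L) stop("expression_fraction_filter: empty cell subset",
                                call. = FALSE)
  v <- m$values[cells, , drop = FALSE]
  ndet <- Matrix::colSums(v > 0)
  need <- ceiling(min_frac * nrow(v))
  m$gene_ids[ndet >= need]
}

#' Two-group Wilcoxon rank-sum differential expression
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of group A vs group B on
#' normalized values, using the normal approximation with tie correction and
#' continuity correction (the default marker-test behavior of single-cell
#' toolkits). Ranking exploits sparsity: zeros share one midrank block and
#' only non-zero entries are sorted. The fold-change is computed on de-logged
#' means with a pseudo-count of 1:
#' `log2fc = log2((mean(expm1 xA) + 1) / (mean(expm1 xB) + 1))`.
#'
#' With `exact = TRUE` (small groups), the p-value is instead the exact
#' permutation tail of the rank-sum statistic, enumerated over all
#' assignments of cells to group A.
#'
#' @param m normalized-layer `count_matrix`.
#' @param cells_a,cells_b disjoint cell index/id vectors for the two groups.
#' @param genes genes to test (default: all genes of `m`).
#' @param p_adj_cutoff,lfc_cutoff DEG gates: `p_adj < p_adj_cutoff` and
#'   `|log2fc| >= lfc_cutoff`.
#' @param exact use exhaustive enumeration of the rank-sum null (only
#'   feasible for small groups).
#' @return data.frame: gene, log2fc, p, p_adj, pct_a, pct_b, is_deg.
#' @export
wilcoxon_de <- function(m, cells_a, cells_b, genes = NULL,
                        p_adj_cutoff = 0.05, lfc_cutoff = 0.5, exact = FALSE) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "normalized") stop("wilcoxon_de: expects the normalized layer",
                                    call. = FALSE)
  ia <- resolve_cells(m, cells_a)
  ib <- resolve_cells(m, cells_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("wilcoxon_de: empty group", call. = FALSE)
  }
  if (length(intersect(ia, ib))) stop("wilcoxon_de: groups overlap", call. = FALSE)
  if (min(length(ia), length(ib)) < 3) {
    warning("wilcoxon_de: a group has fewer than 3 cells", call. = FALSE)
  }
  gi <- if (is.null(genes)) seq_len(n_genes(m)) else match(genes, m$gene_ids)
  nA <- length(ia); nB <- length(ib); n <- nA + nB
  sub <- m$values[c(ia, ib), gi, drop = FALSE]
  grpA <- seq_len(nA)

  tri <- methods::as(sub, "TsparseMatrix")
  dt <- data.table::data.table(g = tri@j + 1L, cell = tri@i + 1L, v = tri@x)
  dt <- dt[v != 0]
  dt[, inA := cell <= nA]

  stat_one <- function(v, inA) {
    nz <- length(v)
    z <- n - nz
    r_nz <- z + rank(v, ties.method = "average")
    nzA <- sum(inA)
    RA <- (nA - nzA) * (z + 1) / 2 + sum(r_nz[inA])
    # tie correction: zero block plus tied non-zero values
    tt <- as.numeric(table(v))
    ties3 <- sum(tt^3 - tt) + (z^3 - z)
    U <- RA - nA * (nA + 1) / 2
    mu <- nA * nB / 2
    s2 <- nA * nB / 12 * ((n + 1) - ties3 / (n * (n - 1)))
    sumA <- sum(expm1(v[inA]))
    sumB <- sum(expm1(v[!inA]))
    list(U = U, s2 = s2, nzA = nzA, nzB = nz - nzA, sumA = sumA, sumB = sumB)
  }
  res <- dt[, stat_one(v, inA), by = g]
  # genes with no non-zero entries in the subset never enter dt
  full <- data.table::data.table(g = seq_along(gi))
  res <- res[full, on = "g"]
  res[is.na(U), `:=`(U = nA * nB / 2, s2 = 0, nzA = 0L, nzB = 0L,
                     sumA = 0, sumB = 0)]
  data.table::setorder(res, g)

  if (exact) {
    p <- exact_ranksum_p(sub, nA)
  } else {
    dU <- res$U - nA * nB / 2
    zstat <- ifelse(res$s2 > 0, (dU - 0.5 * sign(dU)) / sqrt(res$s2), 0)
    p <- pmin(1, 2 * stats::pnorm(-abs(zstat)))
  }
  log2fc <- log2((res$sumA / nA + 1) / (res$sumB / nB + 1))
  out <- data.frame(
    gene = m$gene_ids[gi], log2fc = log2fc, p = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    pct_a = res$nzA / nA, pct_b = res$nzB / nB,
    stringsAsFactors = FALSE
  )
  out$is_deg <- out$p_adj < p_adj_cutoff & abs(out$log2fc) >= lfc_cutoff
  out
}

resolve_cells <- function(m, cells) {
  if (is.character(cells)) {
    i <- match(cells, m$cell_ids)
    if (anyNA(i)) stop("unknown cell id(s)", call. = FALSE)
    i
  } else if (is.logical(cells)) {
    which(cells)
  } else {
    as.integer(cells)
  }
}

# exact permutation p of the rank-sum statistic over all assignments of nA
# cells to group A (columns of `sub` are genes; first nA rows are group A)
exact_ranksum_p <- function(sub, nA) {
  x <- as.matrix(sub)
  n <- nrow(x)
  combs <- utils::combn(n, nA)
  apply(x, 2, function(v) {
    r <- rank(v, ties.method = "average")
    RA_obs <- sum(r[seq_len(nA)])
    mu <- nA * (n + 1) / 2
    RA_all <- colSums(matrix(r[combs], nrow = nA))
    mean(abs(RA_all - mu) >= abs(RA_obs - mu) - 1e-12)
  })
}

#' Aggregate single-cell counts into pseudobulk profiles
#'
#' Gene-wise sum of raw counts per group. Groups with no cells are dropped
#' with a warning.
#'
#' @param m raw-layer `count_matrix`.
#' @param grouping factor/vector assigning each cell to exactly one group.
#' @return list of class `pseudobulk`: `matrix` (groups x genes),
#'   `n_cells` (named count per group).
#' @export
pseudobulk_aggregate <- function(m, grouping) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "raw") stop("pseudobulk_aggregate: expects the raw layer",
                             call. = FALSE)
  if (length(grouping) != n_cells(m)) {
    stop("pseudobulk_aggregate: grouping length mismatch", call. = FALSE)
  }
  f <- if (is.factor(grouping)) grouping else factor(grouping)
  if (any(table(f) == 0)) {
    warning("pseudobulk_aggregate: empty group(s) dropped", call. = FALSE)
    f <- droplevels(f)
  }
  ind <- Matrix::sparseMatrix(i = as.integer(f), j = seq_len(n_cells(m)), x = 1,
                              dims = c(nlevels(f), n_cells(m)))
  pb <- as.matrix(ind %*% m$values)
  rownames(pb) <- levels(f)
  colnames(pb) <- m$gene_ids
  structure(list(matrix = pb, n_cells = table(f)), class = "pseudobulk")
}

#' Pseudobulk negative-binomial likelihood-ratio differential expression
#'
#' Per gene, a negative-binomial log-linear model with `offset = log(library
#' size)` is fit to the pseudobulk counts; the condition coefficient is tested
#' with a likelihood-ratio test against the nested model without condition
#' (chi-square, df = 1). When `patient` is supplied the design is paired:
#' both models carry patient blocks. The per-gene dispersion is a
#' method-of-moments estimate shrunk toward the trimmed-mean common dispersion
#' with weight `n / (n + 10)` (n = number of pseudobulk samples).
#'
#' @param pb `pseudobulk` from [pseudobulk_aggregate()].
#' @param condition two-level factor, one entry per pseudobulk row. The
#'   reported `log2fc` is second level vs first level.
#' @param patient optional blocking factor (paired designs).
#' @param p_adj_cutoff,lfc_cutoff DEG gates as in [wilcoxon_de()].
#' @return data.frame: gene, log2fc, p, p_adj, dispersion, is_deg.
#' @export
nb_lrt_de <- function(pb, condition, patient = NULL,
                      p_adj_cutoff = 0.05, lfc_cutoff = 0.5) {
  stopifnot(inherits(pb, "pseudobulk"))
  y <- pb$matrix
  if (any(y != round(y))) stop("nb_lrt_de: pseudobulk values must be integer counts",
                               call. = FALSE)
  condition <- factor(condition)
  if (nlevels(condition) != 2) stop("nb_lrt_de: condition must have two levels",
                                    call. = FALSE)
  if (length(condition) != nrow(y)) stop("nb_lrt_de: condition length mismatch",
                                         call. = FALSE)
  n <- nrow(y)
  s <- rowSums(y)
  off <- log(s)
  # method-of-moments dispersion on library-size-adjusted counts
  z <- y * mean(s) / s
  phi <- mom_dispersion(z, condition)
  phi_common <- trimmed_common_dispersion(phi)
  phi_shr <- ifelse(is.na(phi), phi_common,
                    (n * phi + 10 * phi_common) / (n + 10))
  phi_shr <- pmax(phi_shr, 1e-4)

  has_patient <- !is.null(patient)
  if (has_patient) patient <- factor(patient)
  res <- matrix(NA_real_, ncol(y), 2,
                dimnames = list(colnames(y), c("log2fc", "p")))
  cond_name <- paste0("condition", levels(condition)[2])
  for (j in seq_len(ncol(y))) {
    yy <- y[, j]
    fam <- MASS::negative.binomial(theta = 1 / phi_shr[j])
    fit <- tryCatch({
      if (has_patient) {
        f1 <- stats::glm(yy ~ condition + patient + offset(off), family = fam)
        f0 <- stats::glm(yy ~ patient + offset(off), family = fam)
      } else {
        f1 <- stats::glm(yy ~ condition + offset(off), family = fam)
        f0 <- stats::glm(yy ~ 1 + offset(off), family = fam)
      }
      lrt <- max(0, f0$deviance - f1$deviance)
      c(stats::coef(f1)[[cond_name]] / log(2),
        stats::pchisq(lrt, df = 1, lower.tail = FALSE))
    }, error = function(e) c(NA_real_, NA_real_))
    res[j, ] <- fit
  }
  out <- data.frame(gene = colnames(y), log2fc = res[, "log2fc"], p = res[, "p"],
                    p_adj = stats::p.adjust(res[, "p"], method = "BH"),
                    dispersion = phi_shr, stringsAsFactors = FALSE)
  out$is_deg <- !is.na(out$p_adj) & out$p_adj < p_adj_cutoff &
    abs(out$log2fc) >= lfc_cutoff
  rownames(out) <- NULL
  out
}

# per-gene method-of-moments NB dispersion from within-condition moments;
# NA where no within-condition replication or zero mean
mom_dispersion <- function(z, condition) {
  lv <- levels(condition)
  n1 <- sum(condition == lv[1]); n2 <- sum(condition == lv[2])
  if (n1 < 2 || n2 < 2) {
    # fall back to cross-sample moments (conservative: includes the condition
    # effect in the variance)
    m <- colMeans(z)
    v <- apply(z, 2, stats::var)
  } else {
    z1 <- z[condition == lv[1], , drop = FALSE]
    z2 <- z[condition == lv[2], , drop = FALSE]
    m <- colMeans(z)
    v <- ((n1 - 1) * apply(z1, 2, stats::var) +
            (n2 - 1) * apply(z2, 2, stats::var)) / (n1 + n2 - 2)
  }
  phi <- (v - m) / m^2
  phi[!is.finite(phi)] <- NA
  pmax(phi, 0)
}

trimmed_common_dispersion <- function(phi) {
  ok <- phi[!is.na(phi)]
  if (!length(ok)) return(0.1)
  max(mean(ok, trim = 0.1), 1e-4)
}

#' Gene-label permutation test for cross-patient DEG recurrence
#'
#' Observed statistic: the number of genes called DEG in at least `k` pairs.
#' Null draws resample each pair's DEG set uniformly without replacement from
#' that pair's own tested-gene universe, preserving the per-pair DEG counts.
#' The p-value is one-sided with the add-one estimator.
#'
#' @param deg_sets list of character vectors: DEGs per pair.
#' @param universes list of character vectors: tested genes per pair
#'   (`deg_sets[[i]]` must be a subset).
#' @param B permutations (default 10000).
#' @param seed integer seed.
#' @param k recurrence threshold (default 2).
#' @return list: `observed` (count of genes DEG in >= k pairs), `p`,
#'   `multiplicity` (observed histogram: genes DEG in exactly m pairs),
#'   `null_stats` (S_b draws), `B`, `k`, `seed`.
#' @export
recurrence_permutation_test <- function(deg_sets, universes, B = 10000,
                                        seed = 1L, k = 2) {
  stopifnot(length(deg_sets) == length(universes), length(deg_sets) >= 1)
  for (i in seq_along(deg_sets)) {
    if (length(universes[[i]]) == 0L) {
      stop("recurrence_permutation_test: empty universe", call. = FALSE)
    }
    if (!all(deg_sets[[i]] %in% universes[[i]])) {
      stop("recurrence_permutation_test: DEG set ", i,
           " is not a subset of its universe", call. = FALSE)
    }
  }
  all_genes <- unique(unlist(universes))
  uni_idx <- lapply(universes, match, table = all_genes)
  m_i <- lengths(deg_sets)
  n_pairs <- length(deg_sets)

  mult <- table(factor(unlist(lapply(deg_sets, unique)), levels = all_genes))
  multiplicity <- table(factor(mult[mult > 0], levels = seq_len(n_pairs)))
  observed <- sum(mult >= k)

  set.seed(seed)
  G <- length(all_genes)
  null_stats <- integer(B)
  counts <- integer(G)
  for (b in seq_len(B)) {
    counts[] <- 0L
    for (i in seq_len(n_pairs)) {
      if (m_i[i] == 0L) next
      pick <- uni_idx[[i]][sample.int(length(uni_idx[[i]]), m_i[i])]
      counts[pick] <- counts[pick] + 1L
    }
    null_stats[b] <- sum(counts >= k)
  }
  p <- (1 + sum(null_stats >= observed)) / (B + 1)
  list(observed = observed, p = p, multiplicity = multiplicity,
       null_stats = null_stats, B = B, k = k, seed = seed)
}
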