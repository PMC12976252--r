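#' Cross-tabulate cluster composition by time point
#'
#' @param timepoint character vector per cell, values in
#'   \{"indolent", "active"\}.
#' @param clusters cluster label per cell (any atomic type; must be non-empty).
#' @return data.frame of class `composition_table`: cluster, n_indolent,
#'   n_active; attributes `N_I`, `N_A`.
#' @export
compose <- function(timepoint, clusters) {
  if (length(clusters) == 0L || length(timepoint) == 0L) {
    stop("compose: empty input", call. = FALSE)
  }
  if (length(clusters) != length(timepoint)) {
    stop("compose: length mismatch", call. = FALSE)
  }
  bad <- setdiff(unique(timepoint), c("indolent", "active"))
  if (length(bad)) stop("compose: unknown timepoint(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  tab <- table(cluster = clusters, timepoint = factor(timepoint,
                                                      c("indolent", "active")))
  out <- data.frame(cluster = rownames(tab),
                    n_indolent = as.integer(tab[, "indolent"]),
                    n_active = as.integer(tab[, "active"]),
                    stringsAsFactors = FALSE)
  attr(out, "N_I") <- sum(out$n_indolent)
  attr(out, "N_A") <- sum(out$n_active)
  class(out) <- c("composition_table", "data.frame")
  out
}

# log2 proportion fold-difference (active vs indolent) with a Haldane-style
# +0.5 continuity correction per cluster count so empty clusters stay finite:
# p_T(c) = (n_T(c) + 0.5) / (N_T + 0.5 K)
log2fd_from_counts <- function(n_i, n_a, N_I, N_A, K) {
  p_i <- (n_i + 0.5) / (N_I + 0.5 * K)
  p_a <- (n_a + 0.5) / (N_A + 0.5 * K)
  log2(p_a / p_i)
}

#' Observed log2 fold-difference in cluster proportion
#'
#' `log2(p_active / p_indolent)` for one cluster of a composition table, with
#' a +0.5 continuity correction on counts (and 0.5 K on totals) so the
#' statistic is finite for empty cells.
#'
#' @param tab a `composition_table` from [compose()].
#' @param cluster cluster identifier (matched against `tab$cluster`).
#' @return numeric scalar.
#' @export
log2_fold_difference <- function(tab, cluster) {
  i <- match(as.character(cluster), tab$cluster)
  if (is.na(i)) stop("log2_fold_difference: unknown cluster", call. = FALSE)
  log2fd_from_counts(tab$n_indolent[i], tab$n_active[i],
                     attr(tab, "N_I"), attr(tab, "N_A"), nrow(tab))
}

#' Permutation test for cluster abundance shifts within a longitudinal pair
#'
#' Tests, per cluster, whether the cluster's share of cells differs between
#' the indolent and the active time point beyond what the pair's global
#' time-point composition predicts. The null is generated by randomly
#' permuting the time-point labels across all cells of the pair (cluster
#' sizes and the overall indolent/active totals are fixed), which makes the
#' per-cluster indolent counts multivariate-hypergeometric; draws are sampled
#' exactly from that law. The two-sided p-value uses the add-one estimator
#' `(1 + #\{|log2fd_b| >= |obs|\}) / (B + 1)`; FDR is Benjamini-Hochberg
#' across the clusters of the pair.
#'
#' @param timepoint per-cell time point in \{"indolent", "active"\}.
#' @param clusters per-cell cluster label.
#' @param B number of permutations (default 10000; must be >= 100).
#' @param seed integer seed.
#' @return data.frame of class `cluster_shift_result`: cluster, n_indolent,
#'   n_active, obs_log2fd, p_perm, fdr; attributes `B` and `seed`.
#' @export
proportion_shift_test <- function(timepoint, clusters, B = 10000, seed = 1L) {
  if (B < 100) stop("proportion_shift_test: B must be >= 100", call. = FALSE)
  tab <- compose(timepoint, clusters)
  N_I <- attr(tab, "N_I"); N_A <- attr(tab, "N_A")
  if (N_I == 0 || N_A == 0) {
    stop("proportion_shift_test: both time points must be present", call. = FALSE)
  }
  K <- nrow(tab)
  sizes <- tab$n_indolent + tab$n_active
  obs <- log2fd_from_counts(tab$n_indolent, tab$n_active, N_I, N_A, K)

  set.seed(seed)
  # sequential multivariate-hypergeometric sampling of per-cluster indolent
  # counts under label permutation
  null_i <- matrix(0, nrow = B, ncol = K)
  remaining_cells <- sum(sizes)
  remaining_I <- rep(N_I, B)
  for (c in seq_len(K - 1L)) {
    draw <- stats::rhyper(B, m = sizes[c], n = remaining_cells - sizes[c],
                          k = remaining_I)
    null_i[, c] <- draw
    remaining_I <- remaining_I - draw
    remaining_cells <- remaining_cells - sizes[c]
  }
  null_i[, K] <- remaining_I
  null_a <- matrix(sizes, B, K, byrow = TRUE) - null_i
  null_fd <- abs(log2fd_from_counts(null_i, null_a, N_I, N_A, K))
  # tie tolerance: identical count configurations must compare equal even
  # though |log2(a/b)| and log2(b/a) differ in the last ulp
  exceed <- colSums(null_fd >= matrix(abs(obs) - 1e-9, B, K, byrow = TRUE))
  p <- (1 + exceed) / (B + 1)
  res <- data.frame(cluster = tab$cluster, n_indolent = tab$n_indolent,
                    n_active = tab$n_active, obs_log2fd = obs, p_perm = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(res, "B") <- B
  attr(res, "seed") <- seed
  class(res) <- c("cluster_shift_result", "data.frame")
  res
}

#' Classify clusters as expanding, shrinking, or stable
#'
#' Expanding: FDR < `alpha` and observed log2 fold-difference >= `tau`;
#' shrinking: FDR < `alpha` and log2 fold-difference <= -`tau`; otherwise
#' stable.
#'
#' @param res result of [proportion_shift_test()].
#' @param alpha FDR cutoff (default 0.05).
#' @param tau log2 fold-difference cutoff (default 1).
#' @return `res` with an added `class` column.
#' @export
classify_clusters <- function(res, alpha = 0.05, tau = 1.0) {
  cls <- rep("stable", nrow(res))
  cls[res$fdr < alpha & res$obs_log2fd >= tau] <- "expanding"
  cls[res$fdr < alpha & res$obs_log2fd <= -tau] <- "shrinking"
  res$class <- cls
  res
}
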