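#' Quality-control filter on cells
#'
#' Keeps cells with at least `min_features` and at most `max_features`
#' detected genes (count > 0) and a mitochondrial count fraction strictly
#' below `max_mito`. A cell with zero total counts has `pct_mito` defined as
#' 0 and is removed for too few features.
#'
#' @param m raw-layer `count_matrix`.
#' @param annotation gene annotation data.frame with `gene_id` and
#'   `is_mitochondrial`.
#' @param min_features,max_features detected-gene bounds (inclusive).
#' @param max_mito mitochondrial fraction bound (exclusive).
#' @return list with `counts` (filtered `count_matrix`) and `report`
#'   (data.frame: cell_id, n_features, pct_mito, kept, reasons), plus
#'   `n_cells_in` / `n_cells_kept` attributes on the report.
#' @export
qc_filter <- function(m, annotation, min_features = 250, max_features = 4500,
                      max_mito = 0.20) {
  stopifnot(inherits(m, "count_matrix"), m$layer == "raw")
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "is_mitochondrial") %in% names(annotation))) {
    stop("qc_filter: annotation with gene_id and is_mitochondrial required",
         call. = FALSE)
  }
  mito_genes <- annotation$gene_id[annotation$is_mitochondrial]
  mito_cols <- which(m$gene_ids %in% mito_genes)
  nf <- Matrix::rowSums(m$values > 0)
  tot <- Matrix::rowSums(m$values)
  mito <- if (length(mito_cols)) {
    Matrix::rowSums(m$values[, mito_cols, drop = FALSE])
  } else rep(0, n_cells(m))
  pct_mito <- ifelse(tot > 0, mito / tot, 0)
  low <- nf < min_features
  high <- nf > max_features
  hm <- pct_mito >= max_mito
  kept <- !(low | high | hm)
  reasons <- character(n_cells(m))
  rl <- cbind(low_features = low, high_features = high, high_mito = hm)
  reasons[!kept] <- apply(rl[!kept, , drop = FALSE], 1,
                          function(r) paste(colnames(rl)[r], collapse = ","))
  report <- data.frame(cell_id = m$cell_ids, n_features = as.integer(nf),
                       pct_mito = pct_mito, kept = kept, reasons = reasons,
                       stringsAsFactors = FALSE)
  attr(report, "n_cells_in") <- n_cells(m)
  attr(report, "n_cells_kept") <- sum(kept)
  if (!any(kept)) {
    warning("qc_filter: all cells removed", call. = FALSE)
    out <- subset_counts(m, cells = which(kept))
  } else {
    out <- subset_counts(m, cells = which(kept))
  }
  list(counts = out, report = report)
}

#' Library-size normalization with log1p transform
#'
#' Each cell's counts are divided by the cell total, scaled by `scale_factor`
#' and transformed with the natural `log1p`; zeros stay zero so sparsity is
#' preserved. Run after [qc_filter()]: cells with zero total counts are an
#' error.
#'
#' @param m raw-layer `count_matrix`.
#' @param scale_factor scaling constant (default 1e4).
#' @return normalized-layer `count_matrix`.
#' @export
normalize_log1p <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "raw") stop("normalize_log1p: expects the raw layer", call. = FALSE)
  tot <- Matrix::rowSums(m$values)
  if (any(tot == 0)) {
    stop("normalize_log1p: zero-total cell(s): ",
         paste(utils::head(m$cell_ids[tot == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  v <- methods::as(m$values, "TsparseMatrix")
  v@x <- log1p(scale_factor * v@x / tot[v@i + 1L])
  count_matrix(v, m$gene_ids, m$cell_ids, layer = "normalized")
}

#' PCA embedding on scaled highly-variable genes
#'
#' Restricts to the `n_hvg` most variable genes (variance of normalized
#' values), standardizes each gene to zero mean and unit variance with values
#' clipped at +/-10, then computes an exact PCA (eigendecomposition of the
#' gene-gene covariance). Component signs are fixed by making the
#' largest-magnitude entry of each loading vector positive, so the embedding
#' is fully deterministic.
#'
#' @param m normalized-layer `count_matrix`.
#' @param n_components number of components retained (default 15).
#' @param n_hvg number of highly-variable genes (default 2000).
#' @return list of class `embedding`: `coordinates` (cells x n_components),
#'   `n_components`, `sdev` (component standard deviations), `genes` (HVGs
#'   used).
#' @export
pca_embed <- function(m, n_components = 15, n_hvg = 2000) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "normalized") stop("pca_embed: expects the normalized layer", call. = FALSE)
  if (n_components >= min(n_cells(m), n_genes(m))) {
    stop("pca_embed: n_components must be < min(cells, genes)", call. = FALSE)
  }
  if (n_genes(m) < n_hvg) {
    warning("pca_embed: fewer genes than n_hvg; using all genes", call. = FALSE)
    n_hvg <- n_genes(m)
  }
  v <- m$values
  n <- nrow(v)
  mu <- Matrix::colMeans(v)
  ex2 <- Matrix::colMeans(v^2)
  gvar <- (ex2 - mu^2) * n / (n - 1)
  hvg <- order(gvar, decreasing = TRUE)[seq_len(n_hvg)]
  hvg <- sort(hvg)
  x <- as.matrix(v[, hvg, drop = FALSE])
  sd_g <- sqrt(gvar[hvg])
  sd_g[sd_g == 0] <- 1
  x <- sweep(x, 2, mu[hvg], "-")
  x <- sweep(x, 2, sd_g, "/")
  x[x > 10] <- 10
  x[x < -10] <- -10
  # exact PCA: eigen of the covariance of the clipped, scaled matrix
  xc <- sweep(x, 2, colMeans(x), "-")
  cv <- crossprod(xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  k <- n_components
  load <- eg$vectors[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2, function(u) sign(u[which.max(abs(u))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, "*")
  coords <- xc %*% load
  rownames(coords) <- m$cell_ids
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords, n_components = k,
                 sdev = sqrt(pmax(eg$values[seq_len(k)], 0)), genes = m$gene_ids[hvg]),
            class = "embedding")
}

# blocked exact k-nearest neighbours (Euclidean), self included
knn_indices <- function(x, k) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  idx <- matrix(0L, n, k)
  block <- max(1L, min(n, floor(2e7 / n)))
  start <- 1L
  while (start <= n) {
    end <- min(n, start + block - 1L)
    d2 <- outer(sq[start:end], sq, "+") - 2 * tcrossprod(x[start:end, , drop = FALSE], x)
    for (i in seq_len(end - start + 1L)) {
      d2[i, start + i - 1L] <- -Inf          # self is always nearest
      idx[start + i - 1L, ] <- order(d2[i, ])[seq_len(k)]
    }
    start <- end + 1L
  }
  idx
}

#' Shared-nearest-neighbor modularity clustering
#'
#' Builds the k-nearest-neighbor graph (Euclidean distance in the embedding,
#' self included among the k neighbors), weights edges by the Jaccard overlap
#' of neighbor sets, prunes weights below `prune` (default 1/15), and runs
#' seeded modularity community detection (Louvain) at the given resolution.
#' Labels are 0-based and relabeled by decreasing cluster size.
#'
#' @param embedding an `embedding` (or bare matrix of coordinates).
#' @param k_neighbors neighbors per cell (default 20).
#' @param resolution modularity resolution parameter.
#' @param prune Jaccard cutoff below which SNN edges are dropped.
#' @param seed integer seed for the community detection.
#' @return integer vector of 0-based cluster labels, one per cell.
#' @export
snn_cluster <- function(embedding, k_neighbors = 20, resolution = 1.5,
                        prune = 1 / 15, seed = 1L) {
  x <- if (inherits(embedding, "embedding")) embedding$coordinates else as.matrix(embedding)
  n <- nrow(x)
  if (k_neighbors >= n) stop("snn_cluster: k_neighbors must be < number of cells",
                             call. = FALSE)
  k <- k_neighbors
  nn <- knn_indices(x, k)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nn)),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- methods::as(shared, "TsparseMatrix")
  jac <- shared@x / (2 * k - shared@x)
  keep <- jac >= prune & shared@i != shared@j
  g <- igraph::graph_from_data_frame(
    data.frame(from = shared@i[keep] + 1L, to = shared@j[keep] + 1L,
               weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "first"))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  relabel_by_size(as.integer(memb))
}

# 0-based labels ordered by decreasing cluster size (ties: first occurrence)
relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab) - 1L, names(tab))
  as.integer(map[as.character(labels)])
}
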