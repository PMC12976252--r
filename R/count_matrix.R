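#' Construct a cells x genes count matrix container
#'
#' Central in-memory container for UMI counts. The matrix is stored cells x
#' genes (per-cell operations dominate the pipeline); 10x-style triplet files
#' on disk are genes x cells and are transposed on read. The `layer` flag
#' distinguishes raw integer UMI counts from normalized (log1p) values.
#'
#' @param values matrix or sparse Matrix, cells x genes, non-negative.
#' @param gene_ids character vector of unique gene symbols (columns).
#' @param cell_ids character vector of unique cell barcodes (rows).
#' @param layer `"raw"` (integer counts) or `"normalized"`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, gene_ids, cell_ids, layer = c("raw", "normalized")) {
  layer <- match.arg(layer)
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids)) {
    stop("count_matrix: dimensions do not match id lists", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("count_matrix: duplicate gene_ids", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("count_matrix: duplicate cell_ids", call. = FALSE)
  x <- values@x
  if (length(x) && min(x) < 0) stop("count_matrix: negative entries", call. = FALSE)
  if (layer == "raw" && length(x) && any(x != round(x))) {
    stop("count_matrix: raw layer requires integer counts", call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids, layer = layer),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d cells x %d genes [%s layer], %d non-zero entries\n",
    n_cells(x), n_genes(x), x$layer, length(x$values@x)
  ))
  invisible(x)
}

#' Number of cells / genes in a count matrix
#' @param m a `count_matrix`.
#' @return integer scalar.
#' @export
n_cells <- function(m) nrow(m$values)

#' @rdname n_cells
#' @export
n_genes <- function(m) ncol(m$values)

#' Subset a count matrix by cells and/or genes
#'
#' @param m a `count_matrix`.
#' @param cells,genes logical, integer, or character index into cells / genes.
#' @return a `count_matrix` with the same layer.
#' @export
subset_counts <- function(m, cells = NULL, genes = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  ci <- if (is.null(cells)) seq_len(n_cells(m)) else cells
  gi <- if (is.null(genes)) seq_len(n_genes(m)) else genes
  v <- m$values[ci, gi, drop = FALSE]
  count_matrix(v, colnames(v), rownames(v), layer = m$layer)
}

#' Read a 10x-style triplet directory into a count matrix
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate, genes x cells),
#' `features.tsv` and `barcodes.tsv`. Gene symbols are taken from the symbol
#' column of the features file (second column when present, else first);
#' duplicate symbols are disambiguated deterministically by suffixing
#' `".1"`, `".2"`, ... in file order.
#'
#' @param directory path containing the three files.
#' @return raw-layer `count_matrix`, cells x genes.
#' @export
read_counts_triplet <- function(directory) {
  mtx <- file.path(directory, "matrix.mtx")
  feat <- file.path(directory, "features.tsv")
  bc <- file.path(directory, "barcodes.tsv")
  for (f in c(mtx, feat, bc)) {
    if (!file.exists(f)) stop("read_counts_triplet: missing file ", f, call. = FALSE)
  }
  m <- Matrix::readMM(mtx)
  ft <- utils::read.table(feat, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  symbols <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
  barcodes <- readLines(bc)
  barcodes <- barcodes[nzchar(barcodes)]
  # barcodes may carry extra TSV columns; keep first field
  barcodes <- vapply(strsplit(barcodes, "\t"), `[[`, character(1), 1L)
  if (nrow(m) != length(symbols) || ncol(m) != length(barcodes)) {
    stop(sprintf(
      "read_counts_triplet: MTX is %d x %d but features/barcodes have %d / %d entries",
      nrow(m), ncol(m), length(symbols), length(barcodes)
    ), call. = FALSE)
  }
  if (length(m@x) && any(m@x != round(m@x))) {
    stop("read_counts_triplet: non-integer values in raw matrix", call. = FALSE)
  }
  count_matrix(Matrix::t(m), make_unique_symbols(symbols), barcodes, layer = "raw")
}

# ".1", ".2" suffixes in file order; first occurrence keeps the bare symbol
make_unique_symbols <- function(symbols) {
  dup <- duplicated(symbols)
  if (!any(dup)) return(symbols)
  counts <- new.env(parent = emptyenv())
  out <- symbols
  for (i in seq_along(symbols)) {
    s <- symbols[i]
    k <- if (is.null(counts[[s]])) 0L else counts[[s]]
    if (k > 0L) out[i] <- paste0(s, ".", k)
    counts[[s]] <- k + 1L
  }
  out
}

#' Write a raw count matrix as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket coordinate integer),
#' `features.tsv` (id and symbol columns, identical here) and `barcodes.tsv`.
#'
#' @param m raw-layer `count_matrix`.
#' @param directory output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_counts_triplet <- function(m, directory) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "raw") {
    stop("write_counts_triplet: only the raw layer is written to MTX", call. = FALSE)
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  g <- methods::as(Matrix::t(m$values), "TsparseMatrix")
  mtx <- file.path(directory, "matrix.mtx")
  con <- file(mtx, "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(g), ncol(g), length(g@x))), con)
  if (length(g@x)) {
    o <- order(g@j, g@i)
    writeLines(sprintf("%d %d %d", g@i[o] + 1L, g@j[o] + 1L, as.integer(g@x[o])), con)
  }
  close(con)
  utils::write.table(
    data.frame(id = m$gene_ids, symbol = m$gene_ids),
    file.path(directory, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  writeLines(m$cell_ids, file.path(directory, "barcodes.tsv"))
  invisible(directory)
}

#' Read gene sets from a GMT file
#'
#' MSigDB GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description column is
#' discarded; duplicate genes within a line are deduplicated.
#'
#' @param path GMT file.
#' @return named list of character vectors (one per set, file order).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop(sprintf("read_gene_sets: line %d has fewer than 3 fields", lineno[i]),
           call. = FALSE)
    }
    nms[i] <- fields[1]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a per-cell metadata table
#'
#' Required columns: `cell_id`, `patient_id`, `sample_id`, `timepoint`
#' (one of indolent / active / healthy). Optional: `cell_type`, `cluster`,
#' `n_features`, `pct_mito`. Enforces unique barcodes and that each sample
#' maps to exactly one (patient, timepoint).
#'
#' @param df data.frame of per-cell metadata.
#' @return the validated data.frame (invisibly usable downstream).
#' @export
validate_cell_table <- function(df) {
  need <- c("cell_id", "patient_id", "sample_id", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cell table missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(df$cell_id)) stop("cell table: duplicate cell_ids", call. = FALSE)
  bad <- setdiff(unique(df$timepoint), c("indolent", "active", "healthy"))
  if (length(bad)) stop("cell table: unknown timepoint(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  map <- unique(df[, c("sample_id", "patient_id", "timepoint")])
  if (anyDuplicated(map$sample_id)) {
    stop("cell table: a sample_id maps to more than one (patient, timepoint)",
         call. = FALSE)
  }
  df
}
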