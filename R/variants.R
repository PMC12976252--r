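#' Somatic short-variant retention thresholds
#'
#' Defaults follow the tumor-only retention rule used throughout the
#' WGS analysis: VAF >= 5%, depth >= 10 with >= 3 alt-supporting reads,
#' population allele frequency <= 0.01, dbSNP MAF <= 0.05, TOPMed MAF <= 0.05.
#' Absent population-frequency annotations are treated as 0, i.e. they pass
#' those criteria (tumor-only calling leaves many sites unannotated).
#'
#' @param min_vaf,min_depth,min_alt_reads,max_pop_af,max_dbsnp_maf,max_topmed_maf
#'   thresholds; see Details.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_vaf = 0.05, min_depth = 10, min_alt_reads = 3,
                          max_pop_af = 0.01, max_dbsnp_maf = 0.05,
                          max_topmed_maf = 0.05) {
  stopifnot(min_vaf >= 0, min_vaf <= 1, min_depth >= 0, min_alt_reads >= 0,
            max_pop_af >= 0, max_pop_af <= 1,
            max_dbsnp_maf >= 0, max_dbsnp_maf <= 1,
            max_topmed_maf >= 0, max_topmed_maf <= 1)
  structure(list(min_vaf = min_vaf, min_depth = min_depth,
                 min_alt_reads = min_alt_reads, max_pop_af = max_pop_af,
                 max_dbsnp_maf = max_dbsnp_maf, max_topmed_maf = max_topmed_maf),
            class = "filter_config")
}

#' Read somatic short variants from a VCF into a variant table
#'
#' One row per ALT allele: multi-allelic sites are split. Depth and alt reads
#' come from the first sample's AD field (depth = sum of AD); when AD is
#' absent, DP provides depth and alt reads come from an `AD`-equivalent INFO
#' field is not attempted — AD or DP must be present. Population frequencies
#' are read from configurable INFO keys (Funcotator/VEP dialects differ);
#' absent keys are stored as `NA` and treated as 0 by the retention filter.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @param pop_af_key,dbsnp_key,topmed_key INFO keys carrying gnomAD-style
#'   population AF, dbSNP MAF and TOPMed MAF.
#' @param gene_key INFO key carrying a gene symbol annotation, if any.
#' @return data.frame with columns chrom, pos, ref, alt, depth, alt_reads,
#'   vaf, pop_af, dbsnp_maf, topmed_maf, gene.
#' @export
read_variants <- function(path, pop_af_key = "POPAF", dbsnp_key = "DBSNP_MAF",
                          topmed_key = "TOPMED_MAF", gene_key = "GENE") {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("read_variants: malformed VCF: ", conditionMessage(e),
                             call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(empty_variant_table())
  }
  has_gt <- ncol(vcf@gt) >= 2
  ad <- if (has_gt) vcfR::extract.gt(vcf, element = "AD")[, 1] else rep(NA_character_, n)
  dp <- if (has_gt) suppressWarnings(
    as.numeric(vcfR::extract.gt(vcf, element = "DP")[, 1])) else rep(NA_real_, n)
  info_num <- function(key) {
    v <- tryCatch(vcfR::extract.info(vcf, element = key),
                  error = function(e) rep(NA_character_, n))
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  pop <- info_num(pop_af_key); dbs <- info_num(dbsnp_key); top <- info_num(topmed_key)
  gene <- info_num(gene_key)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    ad_i <- if (!is.na(ad[i])) suppressWarnings(
      as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1]])) else NULL
    if (is.null(ad_i) && is.na(dp[i])) {
      stop("read_variants: record without AD and DP at ",
           fix[i, "CHROM"], ":", fix[i, "POS"], call. = FALSE)
    }
    depth <- if (!is.null(ad_i)) sum(ad_i, na.rm = TRUE) else dp[i]
    alt_reads <- if (!is.null(ad_i) && length(ad_i) >= n_alt + 1) {
      ad_i[1 + seq_len(n_alt)]
    } else rep(NA_real_, n_alt)
    if (any(!is.na(alt_reads) & alt_reads > depth)) {
      stop("read_variants: alt_reads exceed depth at ",
           fix[i, "CHROM"], ":", fix[i, "POS"], call. = FALSE)
    }
    split_num <- function(s) {
      if (is.na(s)) return(rep(NA_real_, n_alt))
      v <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
      if (length(v) == n_alt) v else rep(v[1], n_alt)
    }
    rows[[i]] <- data.frame(
      chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"], alt = alts,
      depth = depth, alt_reads = alt_reads,
      vaf = if (depth > 0) alt_reads / depth else rep(0, n_alt),
      pop_af = split_num(pop[i]), dbsnp_maf = split_num(dbs[i]),
      topmed_maf = split_num(top[i]),
      gene = if (is.na(gene[i])) NA_character_ else gene[i],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_variant_table(out)
  out
}

#' Validate a variant table's internal consistency
#'
#' Enforces `alt_reads <= depth` and `vaf = alt_reads / depth` (when depth is
#' positive) and VAF bounds. Called on read and before filtering; violating
#' records raise a named error.
#'
#' @param variants variant table data.frame.
#' @return the table, invisibly, if valid.
#' @export
validate_variant_table <- function(variants) {
  bad <- which(!is.na(variants$alt_reads) & !is.na(variants$depth) &
                 variants$alt_reads > variants$depth)
  if (length(bad)) {
    stop("variant table: alt_reads exceed depth at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  chk <- which(!is.na(variants$vaf) & variants$depth > 0 &
                 !is.na(variants$alt_reads))
  if (length(chk) &&
      any(abs(variants$vaf[chk] -
                variants$alt_reads[chk] / variants$depth[chk]) > 1e-8)) {
    stop("variant table: vaf inconsistent with alt_reads / depth", call. = FALSE)
  }
  if (any(!is.na(variants$vaf) & (variants$vaf < 0 | variants$vaf > 1))) {
    stop("variant table: vaf outside [0, 1]", call. = FALSE)
  }
  invisible(variants)
}

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), depth = numeric(), alt_reads = numeric(),
             vaf = numeric(), pop_af = numeric(), dbsnp_maf = numeric(),
             topmed_maf = numeric(), gene = character(),
             stringsAsFactors = FALSE)
}

#' Apply the tumor-only short-variant retention filter
#'
#' A variant passes iff all six criteria hold:
#' `vaf >= min_vaf`, `depth >= min_depth`, `alt_reads >= min_alt_reads`,
#' `pop_af <= max_pop_af`, `dbsnp_maf <= max_dbsnp_maf`,
#' `topmed_maf <= max_topmed_maf`. All boundaries are inclusive on the pass
#' side. Missing population frequencies count as 0 (pass). Every failing
#' record lists all violated criteria as reason codes.
#'
#' @param variants data.frame from [read_variants()].
#' @param cfg a [filter_config()].
#' @return the input with columns `verdict` ("pass"/"fail") and `reasons`
#'   (comma-separated codes among low_vaf, low_depth, low_alt_reads,
#'   high_pop_af, high_dbsnp_maf, high_topmed_maf).
#' @export
filter_short_variants <- function(variants, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  validate_variant_table(variants)
  z <- function(x) ifelse(is.na(x), 0, x)
  fails <- cbind(
    low_vaf        = z(variants$vaf) < cfg$min_vaf,
    low_depth      = z(variants$depth) < cfg$min_depth,
    low_alt_reads  = z(variants$alt_reads) < cfg$min_alt_reads,
    high_pop_af    = z(variants$pop_af) > cfg$max_pop_af,
    high_dbsnp_maf = z(variants$dbsnp_maf) > cfg$max_dbsnp_maf,
    high_topmed_maf = z(variants$topmed_maf) > cfg$max_topmed_maf
  )
  variants$verdict <- ifelse(rowSums(fails) == 0, "pass", "fail")
  variants$reasons <- apply(fails, 1, function(r) paste(colnames(fails)[r], collapse = ","))
  variants
}

#' Longitudinal VAF trajectory per gene
#'
#' For each gene in `gene_list`, averages the VAFs of that gene's variants at
#' each time point after matching variants across time points on the exact
#' (chrom, pos, ref, alt) key. A variant present at only one time point
#' contributes VAF 0 at the other time point and is flagged (`n_emergent` /
#' `n_lost`).
#'
#' @param v_indolent,v_active filtered variant tables (pass verdicts used when
#'   a `verdict` column is present).
#' @param gene_list character vector of gene symbols.
#' @return data.frame with gene, n_variants, n_emergent, n_lost,
#'   mean_vaf_indolent, mean_vaf_active, delta.
#' @export
vaf_trajectory <- function(v_indolent, v_active, gene_list) {
  if (length(gene_list) == 0L) stop("vaf_trajectory: empty gene_list", call. = FALSE)
  keep_pass <- function(v) {
    if ("verdict" %in% names(v)) v[v$verdict == "pass", , drop = FALSE] else v
  }
  vi <- keep_pass(v_indolent)
  va <- keep_pass(v_active)
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  ki <- key(vi); ka <- key(va)
  out <- lapply(gene_list, function(g) {
    ii <- which(!is.na(vi$gene) & vi$gene == g)
    ia <- which(!is.na(va$gene) & va$gene == g)
    keys <- union(ki[ii], ka[ia])
    if (length(keys) == 0L) {
      return(data.frame(gene = g, n_variants = 0L, n_emergent = 0L, n_lost = 0L,
                        mean_vaf_indolent = NA_real_, mean_vaf_active = NA_real_,
                        delta = NA_real_, stringsAsFactors = FALSE))
    }
    vaf_i <- vi$vaf[ii][match(keys, ki[ii])]
    vaf_a <- va$vaf[ia][match(keys, ka[ia])]
    n_emergent <- sum(is.na(vaf_i))
    n_lost <- sum(is.na(vaf_a))
    vaf_i[is.na(vaf_i)] <- 0
    vaf_a[is.na(vaf_a)] <- 0
    data.frame(gene = g, n_variants = length(keys), n_emergent = n_emergent,
               n_lost = n_lost,
               mean_vaf_indolent = mean(vaf_i), mean_vaf_active = mean(vaf_a),
               delta = mean(vaf_a) - mean(vaf_i), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a variant table as a minimal VCF 4.2 file
#'
#' Used by the synthetic cohort generator to emit fixtures readable by
#' [read_variants()]. AD/DP go into a single TUMOR sample column; population
#' frequencies and gene symbols into INFO.
#'
#' @param variants variant table (columns as in [read_variants()]).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=POPAF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=DBSNP_MAF,Number=A,Type=Float,Description=\"dbSNP minor allele frequency\">",
    "##INFO=<ID=TOPMED_MAF,Number=A,Type=Float,Description=\"TOPMed minor allele frequency\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR"
  )
  fmt_num <- function(x) ifelse(is.na(x), NA_character_, format(x, scientific = FALSE, trim = TRUE))
  lines <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    info <- c(
      if (!is.na(v$pop_af)) paste0("POPAF=", fmt_num(v$pop_af)),
      if (!is.na(v$dbsnp_maf)) paste0("DBSNP_MAF=", fmt_num(v$dbsnp_maf)),
      if (!is.na(v$topmed_maf)) paste0("TOPMED_MAF=", fmt_num(v$topmed_maf)),
      if (!is.na(v$gene)) paste0("GENE=", v$gene)
    )
    info <- if (length(info)) paste(info, collapse = ";") else "."
    ref_reads <- as.integer(round(v$depth - v$alt_reads))
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "AD:DP",
          paste0(ref_reads, ",", as.integer(round(v$alt_reads)), ":",
                 as.integer(round(v$depth))),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}
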