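test_that("hand-written toy triplet parses to the expected matrix", {
  d <- withr::local_tempdir()
  # genes x cells on disk: 3 genes, 2 cells, entries (1,1)=4 and (2,2)=1
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 4", "2 2 1"),
             file.path(d, "matrix.mtx"))
  writeLines(c("E1\tGA", "E2\tGB", "E3\tGC"), file.path(d, "features.tsv"))
  writeLines(c("BC1", "BC2"), file.path(d, "barcodes.tsv"))
  m <- read_counts_triplet(d)
  expect_equal(n_cells(m), 2)
  expect_equal(n_genes(m), 3)
  expect_equal(m$gene_ids, c("GA", "GB", "GC"))
  expect_equal(m$cell_ids, c("BC1", "BC2"))
  expected <- matrix(0, 2, 3)
  expected[1, 1] <- 4; expected[2, 2] <- 1
  expect_equal(unname(as.matrix(m$values)), expected)
  expect_equal(m$layer, "raw")
})

test_that("empty coordinate section yields an all-zero matrix of right shape", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(d, "matrix.mtx"))
  writeLines(c("E1\tGA", "E2\tGB", "E3\tGC"), file.path(d, "features.tsv"))
  writeLines(c("BC1", "BC2"), file.path(d, "barcodes.tsv"))
  m <- read_counts_triplet(d)
  expect_equal(dim(m$values), c(2L, 3L))
  expect_equal(sum(m$values), 0)
})

test_that("triplet write -> read roundtrip is the identity", {
  m <- make_counts(20, 15, lambda = 1, seed = 3)
  d <- withr::local_tempdir()
  write_counts_triplet(m, d)
  m2 <- read_counts_triplet(d)
  expect_equal(as.matrix(m2$values), as.matrix(m$values))
  expect_identical(m2$gene_ids, m$gene_ids)
  expect_identical(m2$cell_ids, m$cell_ids)
})

test_that("1x1 matrix writes the single coordinate line '1 1 7'", {
  m <- count_matrix(matrix(7L, 1, 1), "G", "C")
  d <- withr::local_tempdir()
  write_counts_triplet(m, d)
  lines <- readLines(file.path(d, "matrix.mtx"))
  expect_equal(lines[3], "1 1 7")
})

test_that("parsing is independent of coordinate record order", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  hdr <- c("%%MatrixMarket matrix coordinate integer general", "2 2 3")
  recs <- c("1 1 2", "2 1 5", "2 2 3")
  for (f in c("features.tsv")) {
    writeLines(c("E1\tGA", "E2\tGB"), file.path(d1, f))
    writeLines(c("E1\tGA", "E2\tGB"), file.path(d2, f))
  }
  writeLines(c("BC1", "BC2"), file.path(d1, "barcodes.tsv"))
  writeLines(c("BC1", "BC2"), file.path(d2, "barcodes.tsv"))
  writeLines(c(hdr, recs), file.path(d1, "matrix.mtx"))
  writeLines(c(hdr, rev(recs)), file.path(d2, "matrix.mtx"))
  expect_equal(as.matrix(read_counts_triplet(d1)$values),
               as.matrix(read_counts_triplet(d2)$values))
})

test_that("duplicate gene symbols get deterministic .1/.2 suffixes", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 1 0"),
             file.path(d, "matrix.mtx"))
  writeLines(c("E1\tTCL1A", "E2\tTCL1A", "E3\tTCL1A"), file.path(d, "features.tsv"))
  writeLines("BC1", file.path(d, "barcodes.tsv"))
  expect_equal(read_counts_triplet(d)$gene_ids,
               c("TCL1A", "TCL1A.1", "TCL1A.2"))
})

test_that("format errors are raised for mismatched or non-integer input", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(d, "matrix.mtx"))
  writeLines(c("E1\tGA", "E2\tGB"), file.path(d, "features.tsv"))  # 2 != 3
  writeLines(c("BC1", "BC2"), file.path(d, "barcodes.tsv"))
  expect_error(read_counts_triplet(d), "features/barcodes")

  writeLines(c("%%MatrixMarket matrix coordinate real general", "2 2 1",
               "1 1 2.5"), file.path(d, "matrix.mtx"))
  expect_error(read_counts_triplet(d), "non-integer")

  nm <- normalize_log1p(make_counts(5, 5))
  expect_error(write_counts_triplet(nm, d), "raw layer")
})

test_that("GMT parsing follows the MSigDB dialect", {
  f <- withr::local_tempfile(lines = c(
    "SETA\tdesc\tG1\tG2",
    "SETB\tdesc\tG3\tG3\tG4"
  ))
  sets <- read_gene_sets(f)
  expect_equal(names(sets), c("SETA", "SETB"))
  expect_equal(sets$SETA, c("G1", "G2"))
  expect_equal(sets$SETB, c("G3", "G4"))   # within-line duplicate counted once

  bad <- withr::local_tempfile(lines = c("SETA\tdesc\tG1", "SETB\tdesc"))
  expect_error(read_gene_sets(bad), "line 2")
})

test_that("gene-set write -> read roundtrips", {
  sets <- list(A = c("G1", "G2"), B = c("G9"))
  f <- withr::local_tempfile()
  write_gene_sets(sets, f)
  expect_equal(read_gene_sets(f), sets)
})

test_that("toy VCF parses with hand-checked fields", {
  v <- read_variants(extdata("variants_toy.vcf"))
  expect_equal(nrow(v), 5)
  # AD=90,10 -> depth 100, alt 10, vaf 0.10
  expect_equal(v$depth[1], 100)
  expect_equal(v$alt_reads[1], 10)
  expect_equal(v$vaf[1], 0.10)
  expect_equal(v$pop_af[1], 0.001)
  expect_true(is.na(v$dbsnp_maf[1]))
  expect_equal(v$gene[2], "JAK3")
  expect_equal(v$dbsnp_maf[3], 0.2)
  expect_equal(v[4, c("chrom", "ref", "alt")],
               data.frame(chrom = "chr2", ref = "T", alt = "C", row.names = 4L))
  expect_equal(v$vaf[5], 0.5)
})

test_that("multi-allelic records split into one row per ALT allele", {
  f <- withr::local_tempfile(lines = c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=POPAF,Number=A,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t50\t.\tA\tT,G\t.\tPASS\tPOPAF=0.1,0.2\tAD\t60,30,10"
  ))
  v <- read_variants(f)
  expect_equal(nrow(v), 2)
  expect_equal(v$chrom, c("chr1", "chr1"))
  expect_equal(v$pos, c(50L, 50L))
  expect_equal(v$alt, c("T", "G"))
  expect_equal(v$depth, c(100, 100))
  expect_equal(v$alt_reads, c(30, 10))
  expect_equal(v$pop_af, c(0.1, 0.2))
})

test_that("variant invariants are enforced", {
  bad <- data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "T",
                    depth = 20, alt_reads = 30, vaf = 1.5,
                    pop_af = NA_real_, dbsnp_maf = NA_real_,
                    topmed_maf = NA_real_, gene = NA_character_)
  expect_error(validate_variant_table(bad), "alt_reads exceed depth")
  bad2 <- transform(bad, alt_reads = 10, vaf = 0.9)
  expect_error(validate_variant_table(bad2), "inconsistent")
  expect_error(filter_short_variants(bad), "alt_reads")
})

test_that("cell table validation catches structural problems", {
  ok <- data.frame(cell_id = c("a", "b"), patient_id = "p1",
                   sample_id = c("s1", "s2"),
                   timepoint = c("indolent", "active"))
  expect_silent(validate_cell_table(ok))
  expect_error(validate_cell_table(ok[, -1]), "missing columns")
  dup <- ok; dup$cell_id <- c("a", "a")
  expect_error(validate_cell_table(dup), "duplicate")
  bad_tp <- ok; bad_tp$timepoint <- c("indolent", "remission")
  expect_error(validate_cell_table(bad_tp), "timepoint")
  clash <- ok; clash$sample_id <- "s1"
  expect_error(validate_cell_table(clash), "more than one")
})
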