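test_that("expression fraction filter applies the ceiling boundary", {
  v <- matrix(0L, 100, 3)
  v[1, 1] <- 5L          # gene 1 in exactly 1 of 100 cells
  v[, 3] <- 1L           # gene 3 everywhere
  v[rowSums(v) == 0, 3] <- 1L
  m <- count_matrix(v, c("one", "zero", "all"), sprintf("c%03d", 1:100))
  expect_equal(expression_fraction_filter(m, min_frac = 0.01), c("one", "all"))
  expect_equal(expression_fraction_filter(m, min_frac = 0), m$gene_ids)
  expect_false("zero" %in% expression_fraction_filter(m, min_frac = 0.01))
  expect_error(expression_fraction_filter(m, cells = integer(0)), "empty")
})

test_that("wilcoxon_de is an exact null on identical groups", {
  v <- matrix(rpois(20 * 10, 2), 20, 10)
  v[rowSums(v) == 0, 1] <- 1L
  vv <- rbind(v, v)
  m <- count_matrix(vv, sprintf("g%02d", 1:10), sprintf("c%02d", 1:40))
  nm <- normalize_log1p(m)
  de <- wilcoxon_de(nm, 1:20, 21:40)
  expect_true(all(de$p == 1))
  expect_true(all(de$log2fc == 0))
  expect_equal(de$pct_a, de$pct_b)
  expect_false(any(de$is_deg))
})

test_that("wilcoxon p-values equal the dense rank-sum oracle", {
  set.seed(5)
  v <- matrix(rpois(100 * 50, 1.2), 100, 50)
  v[rowSums(v) == 0, 1] <- 1L
  m <- count_matrix(v, sprintf("g%02d", 1:50), sprintf("c%03d", 1:100))
  nm <- normalize_log1p(m)
  de <- wilcoxon_de(nm, 1:50, 51:100)
  x <- as.matrix(nm$values)
  p_oracle <- sapply(1:50, function(j) {
    suppressWarnings(wilcox.test(x[1:50, j], x[51:100, j],
                                 exact = FALSE, correct = TRUE)$p.value)
  })
  expect_lt(max(abs(de$p - p_oracle)), 1e-10)
})

test_that("fold-change follows the de-logged pseudo-count formula", {
  # group A constant expm1(x) = 3, group B constant expm1(x) = 1
  xa <- log1p(3); xb <- log1p(1)
  v <- rbind(matrix(xa, 5, 2), matrix(xb, 5, 2))
  m <- count_matrix(v, c("g1", "g2"), sprintf("c%d", 1:10),
                    layer = "normalized")
  de <- wilcoxon_de(m, 1:5, 6:10)
  expect_equal(de$log2fc, c(1, 1))        # log2((3+1)/(1+1))
  expect_equal(de$pct_a, c(1, 1))
})

test_that("wilcoxon p is invariant under monotone transforms of the values", {
  set.seed(9)
  v <- matrix(rpois(40 * 8, 1.5), 40, 8)
  v[rowSums(v) == 0, 1] <- 1L
  m <- count_matrix(v, sprintf("g%d", 1:8), sprintf("c%02d", 1:40))
  nm <- normalize_log1p(m)
  de1 <- wilcoxon_de(nm, 1:20, 21:40)
  m2 <- count_matrix(nm$values * 3, nm$gene_ids, nm$cell_ids,
                     layer = "normalized")   # strictly monotone, keeps zeros
  de2 <- wilcoxon_de(m2, 1:20, 21:40)
  expect_equal(de2$p, de1$p, tolerance = 1e-12)
})

test_that("exact enumeration mode agrees with an independent oracle", {
  set.seed(6)
  v <- matrix(rpois(16 * 20, 1.5), 16, 20)
  v[rowSums(v) == 0, 1] <- 1L
  m <- count_matrix(v, sprintf("g%02d", 1:20), sprintf("c%02d", 1:16))
  nm <- normalize_log1p(m)
  de <- wilcoxon_de(nm, 1:8, 9:16, exact = TRUE)
  x <- as.matrix(nm$values)
  cb <- combn(16, 8)
  oracle <- sapply(1:20, function(j) {
    r <- rank(x[, j])
    mu <- 8 * 17 / 2
    obs <- sum(r[1:8])
    all_sums <- colSums(matrix(r[cb], nrow = 8))
    mean(abs(all_sums - mu) >= abs(obs - mu) - 1e-12)
  })
  expect_lt(max(abs(de$p - oracle)), 1e-12)
})

test_that("group size contracts are enforced", {
  nm <- normalize_log1p(make_counts(10, 5))
  expect_error(wilcoxon_de(nm, integer(0), 1:5), "empty group")
  expect_error(wilcoxon_de(nm, 1:5, 4:8), "overlap")
  expect_warning(wilcoxon_de(nm, 1:2, 3:10), "fewer than 3")
})

test_that("pseudobulk aggregation sums raw counts and conserves mass", {
  v <- rbind(c(2L, 3L), c(0L, 1L), c(5L, 0L))
  m <- count_matrix(v, c("g1", "g2"), c("c1", "c2", "c3"))
  pb <- pseudobulk_aggregate(m, c("A", "A", "B"))
  expect_equal(pb$matrix["A", ], c(g1 = 2, g2 = 4))
  expect_equal(pb$matrix["B", ], c(g1 = 5, g2 = 0))
  expect_equal(sum(pb$matrix), sum(v))
  expect_equal(as.numeric(pb$n_cells), c(2, 1))
  # singleton groups reproduce the cell rows
  pb1 <- pseudobulk_aggregate(m, c("x", "y", "z"))
  expect_equal(unname(pb1$matrix), unname(as.matrix(v) * 1.0))
  expect_warning(pseudobulk_aggregate(m, factor(c("A", "A", "B"),
                                                levels = c("A", "B", "C"))),
                 "empty group")
  expect_error(pseudobulk_aggregate(normalize_log1p(m), c("A", "A", "B")),
               "raw layer")
})

test_that("NB LRT is null on duplicated identical groups and guards input", {
  set.seed(3)
  base <- matrix(rpois(4 * 50, 50), 4, 50,
                 dimnames = list(paste0("s", 1:4), paste0("g", 1:50)))
  y <- rbind(base, base)
  rownames(y) <- paste0("s", 1:8)
  pb <- structure(list(matrix = y, n_cells = rep(1, 8)), class = "pseudobulk")
  cond <- factor(rep(c("A", "B"), each = 4))
  de <- nb_lrt_de(pb, cond)
  expect_true(all(de$p > 0.9, na.rm = TRUE))
  expect_true(all(abs(de$log2fc) < 1e-6, na.rm = TRUE))
  pb_bad <- structure(list(matrix = y + 0.5, n_cells = rep(1, 8)),
                      class = "pseudobulk")
  expect_error(nb_lrt_de(pb_bad, cond), "integer counts")
  expect_error(nb_lrt_de(pb, factor(rep("A", 8))), "two levels")
})

test_that("NB LRT agrees with the edgeR reference on effect calls", {
  skip_if_not_installed("edgeR")
  set.seed(14)
  G <- 300; n <- 6
  q <- rlnorm(G, log(200), 1)
  up <- 1:15; down <- 16:75
  fc <- rep(1, G); fc[up] <- 4; fc[down] <- 0.25
  mu <- outer(rep(1, n), q * 500 / mean(q))
  mu[4:6, ] <- sweep(mu[4:6, ], 2, fc, "*")
  y <- matrix(rnbinom(n * G, mu = mu, size = 10), n, G,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:G)))
  pb <- structure(list(matrix = y, n_cells = rep(1, n)), class = "pseudobulk")
  cond <- factor(rep(c("I", "A"), each = 3), levels = c("I", "A"))
  ours <- nb_lrt_de(pb, cond)
  dge <- edgeR::DGEList(counts = t(y), group = cond)
  dge <- edgeR::calcNormFactors(dge, method = "none")
  design <- model.matrix(~cond)
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmFit(dge, design)
  lrt <- edgeR::glmLRT(fit)
  ref <- lrt$table
  expect_gt(cor(ours$log2fc, ref$logFC), 0.98)
  expect_gt(cor(rank(ours$p), rank(ref$PValue)), 0.9)
  expect_lt(median(abs(ours$log2fc[up] - ref$logFC[up])), 0.2)
})

test_that("BH adjustment reproduces the textbook step-up on a hand vector", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # step-up computed by hand: p_(i) * n / i with cumulative minimum from the top
  expected <- c(0.01, 0.04, 0.084, 0.084, 0.084, 0.1, 0.105714285714286,
                0.216, 0.216, 0.216)
  expect_equal(p.adjust(p, method = "BH"), expected, tolerance = 1e-12)
})

test_that("recurrence test handles the floor case and is order-invariant", {
  sets <- list(a = c("g1", "g2"), b = c("g3", "g4"), c = c("g5"))
  uni <- list(a = paste0("g", 1:20), b = paste0("g", 1:20), c = paste0("g", 1:20))
  r <- recurrence_permutation_test(sets, uni, B = 200, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p, 1)                     # S_b >= 0 always
  r2 <- recurrence_permutation_test(rev(sets), rev(uni), B = 200, seed = 1)
  expect_equal(r2$observed, r$observed)
  r3 <- recurrence_permutation_test(sets, uni, B = 200, seed = 1)
  expect_identical(r$null_stats, r3$null_stats)
  expect_error(recurrence_permutation_test(list(c("g1")), list(character(0))),
               "empty universe")
  expect_error(recurrence_permutation_test(list(c("zz")), list(c("g1"))),
               "subset")
})

test_that("observed multiplicity histogram counts genes by recurrence", {
  sets <- list(p1 = c("g1", "g2", "g3"), p2 = c("g1", "g2"), p3 = c("g1"))
  uni <- replicate(3, paste0("g", 1:50), simplify = FALSE)
  r <- recurrence_permutation_test(sets, uni, B = 100, seed = 2, k = 2)
  expect_equal(as.integer(r$multiplicity), c(1L, 1L, 1L))  # g3 x1, g2 x2, g1 x3
  expect_equal(r$observed, 2)              # g1 and g2 in >= 2 pairs
})
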