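test_that("module score cancels exactly on a constant matrix", {
  v <- matrix(2.5, 30, 40)
  m <- count_matrix(v, sprintf("g%02d", 1:40), sprintf("c%02d", 1:30),
                    layer = "normalized")
  sc <- module_score(m, c("g01", "g05", "g20"), n_bins = 5, seed = 3)
  expect_equal(unname(sc), rep(0, 30))
})

test_that("module score is unbiased for expression-matched random sets", {
  set.seed(20)
  m <- make_counts(200, 400, lambda = 1.5, seed = 20)
  nm <- normalize_log1p(m)
  # gene set drawn at random: expected score 0; average over seed replicates
  gs <- sample(nm$gene_ids, 20)
  reps <- sapply(1:20, function(s) mean(module_score(nm, gs, seed = s)))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps)), 3 * se + 0.01)
})

test_that("module score warns on absent genes and checks n_bins", {
  nm <- normalize_log1p(make_counts(20, 30))
  expect_warning(module_score(nm, c("g001", "NOPE"), seed = 1), "absent")
  expect_error(module_score(nm, "g001", n_bins = 100, seed = 1), "n_bins")
  expect_error(suppressWarnings(module_score(nm, "NOPE", seed = 1)),
               "no gene-set genes")
})

test_that("module score is deterministic per seed", {
  nm <- normalize_log1p(make_counts(50, 100, seed = 4))
  gs <- sprintf("g%03d", 1:10)
  expect_identical(module_score(nm, gs, seed = 7), module_score(nm, gs, seed = 7))
})

test_that("activity score reproduces the two-cluster hand computation", {
  # single-gene set, cluster A higher; equal totals so normalization
  # preserves the ordering. percentile (rank - 0.5)/K -> 0.75 / 0.25
  v <- rbind(c(8L, 2L), c(8L, 2L), c(2L, 8L), c(2L, 8L))
  m <- count_matrix(v, c("gs", "other"), sprintf("c%d", 1:4))
  act <- activity_scores(m, c("A", "A", "B", "B"), list(S = "gs"))
  expect_equal(act["A", "S"], 0.25)
  expect_equal(act["B", "S"], -0.25)
})

test_that("activity scores are 0 on ties and bounded in [-0.5, 0.5]", {
  v <- matrix(3L, 6, 4)
  m <- count_matrix(v, sprintf("g%d", 1:4), sprintf("c%d", 1:6))
  act <- activity_scores(m, rep(c("A", "B", "C"), 2), list(S = c("g1", "g2")))
  expect_equal(unname(act[, "S"]), rep(0, 3))
  set.seed(30)
  for (i in 1:25) {
    K <- sample(2:6, 1)
    v <- matrix(rpois(K * 3 * 12, 2), K * 3, 12)
    v[rowSums(v) == 0, 1] <- 1L
    m <- count_matrix(v, sprintf("g%02d", 1:12), sprintf("c%02d", 1:(K * 3)))
    a <- activity_scores(m, rep(seq_len(K), each = 3),
                         list(S1 = sprintf("g%02d", 1:4),
                              S2 = sprintf("g%02d", 5:12)))
    expect_true(all(a >= -0.5 & a <= 0.5))
  }
})

test_that("activity scores sum to zero over clusters for distinct values", {
  set.seed(31)
  v <- matrix(rpois(12 * 6, 5) + seq_len(12), 12, 6)  # ties unlikely
  m <- count_matrix(v, sprintf("g%d", 1:6), sprintf("c%02d", 1:12))
  a <- activity_scores(m, rep(1:4, each = 3), list(S = c("g1", "g3", "g5")))
  expect_equal(sum(a[, "S"]), 0, tolerance = 1e-12)
  expect_warning(activity_scores(m, rep(1:4, each = 3),
                                 list(S = "g1", NONE = "zz")), "dropped")
})

test_that("metabolic fraction follows the pooled-count definitions", {
  genes <- c("met1", "cod1", "cod2", "nc1")
  ann <- data.frame(gene_id = genes,
                    is_protein_coding = c(TRUE, TRUE, TRUE, FALSE),
                    is_metabolic = c(TRUE, FALSE, FALSE, FALSE))
  v <- rbind(c(5L, 45L, 50L, 99L),       # cell: 5 metabolic / 100 coding
             c(0L, 10L, 10L, 1L))        # cell: 0 / 20
  m <- count_matrix(v, genes, c("c1", "c2"))
  fr <- metabolic_fraction(m, ann, per = "cell")
  expect_equal(unname(fr), c(0.05, 0))
  # doubling counts leaves fractions unchanged
  m2 <- count_matrix(v * 2L, genes, c("c1", "c2"))
  expect_equal(metabolic_fraction(m2, ann, per = "cell"), fr)
  # per-sample = pooled counts = count-weighted mean of per-cell fractions
  fs <- metabolic_fraction(m, ann, per = "sample", sample_id = c("s1", "s1"))
  expect_equal(unname(fs), 5 / 120)
  w <- c(100, 20)
  expect_equal(unname(fs), sum(fr * w) / sum(w))
  # metabolic gene outside coding set is warned about and intersected
  ann2 <- ann; ann2$is_metabolic[4] <- TRUE
  expect_warning(metabolic_fraction(m, ann2, per = "cell"), "not protein-coding")
  # zero coding counts -> missing
  v0 <- rbind(c(0L, 0L, 0L, 7L))
  m0 <- count_matrix(v0, genes, "c1")
  expect_true(is.na(metabolic_fraction(m0, ann, per = "cell")[1]))
})

test_that("mixed permutation test matches the exact sign-flip law when fully paired", {
  set.seed(12)
  n <- 8
  diffs <- rnorm(n, 0.3, 1)
  base <- rnorm(n, 5, 1)
  values <- c(base, base + diffs)
  patient <- rep(paste0("p", 1:n), 2)
  tp <- rep(c("indolent", "active"), each = n)
  res <- sample_mean_permutation_test(values, patient, tp, B = 20000, seed = 5)
  # exact: enumerate all 2^n sign flips of the paired differences
  flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null_stats <- abs(flips %*% diffs / n)
  p_exact <- mean(null_stats >= abs(mean(diffs)) - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(res$p - p_exact), 3 * se + 2 / 20001)
})

test_that("mixed permutation test is calibrated on a paired+unpaired null", {
  set.seed(77)
  B <- 499
  rejections <- replicate(300, {
    vals <- rnorm(16)
    patient <- c(rep(paste0("p", 1:6), 2), paste0("u", 1:4))
    tp <- c(rep(c("indolent", "active"), each = 6),
            c("indolent", "indolent", "active", "active"))
    sample_mean_permutation_test(vals, patient, tp, B = B,
                                 seed = sample.int(1e6, 1))$p < 0.05
  })
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.08)
})

test_that("identical condition values give a null permutation p", {
  vals <- rep(1.7, 8)
  patient <- rep(paste0("p", 1:4), 2)
  tp <- rep(c("indolent", "active"), each = 4)
  res <- sample_mean_permutation_test(vals, patient, tp, B = 500, seed = 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(sample_mean_permutation_test(1:3, c("a", "b", "c"),
                                            c("indolent", "indolent", "active")),
               "fewer than 2")
})

test_that("pseudotime orientation rescales, flips and is involutive", {
  tp <- rep(c("indolent", "active"), each = 5)
  inc <- c(1:5, 6:10)
  o1 <- orient_pseudotime(inc, tp)
  expect_equal(o1, (inc - 1) / 9)          # already oriented: rescale only
  dec <- rev(inc)
  o2 <- orient_pseudotime(dec, tp)
  expect_equal(o2, (inc - 1) / 9)          # flipped
  expect_equal(orient_pseudotime(o2, tp), o2)   # involution / idempotence
  expect_true(all(o1 >= 0 & o1 <= 1))
  expect_warning(o3 <- orient_pseudotime(rep(2, 10), tp), "constant")
  expect_equal(o3, rep(0.5, 10))
  expect_error(orient_pseudotime(1:4, rep("indolent", 4)), "both time points")
})
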