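test_that("log2 fold changes match hand arithmetic on group means", {
  # expm1 means: gene 1 in/out = 2/1 -> lfc 1; gene 2 equal means -> 0;
  # gene 3 zero everywhere -> pseudocounts cancel -> 0
  norm <- norm_from_group_means(mean_a = c(2, 1.5, 0), mean_b = c(1, 1.5, 0))
  lfc <- log2_fold_change(norm, labels_ab(), "A")
  expect_equal(unname(lfc), c(1, 0, 0), tolerance = 1e-6)
  expect_error(log2_fold_change(norm, labels_ab(), "Z"), "unknown cluster")
})

test_that("swapping the target group negates lfc and leaves p-values unchanged", {
  set.seed(11)
  norm <- matrix(round(rexp(60), 2), 6, 10,
                 dimnames = list(sprintf("g%d", 1:6), sprintf("c%02d", 1:10)))
  labels <- tibble::tibble(cell_id = colnames(norm),
                           cluster = factor(rep(c("A", "B"), each = 5)))
  lfc_a <- log2_fold_change(norm, labels, "A")
  lfc_b <- log2_fold_change(norm, labels, "B")
  expect_equal(lfc_a, -lfc_b, tolerance = 1e-9)

  wa <- wilcoxon_one_vs_rest(norm, labels, "A")
  wb <- wilcoxon_one_vs_rest(norm, labels, "B")
  expect_equal(wa$p_raw, wb$p_raw, tolerance = 1e-12)

  ta <- ttest_one_vs_rest(norm, labels, "A")
  tb <- ttest_one_vs_rest(norm, labels, "B")
  expect_equal(ta$p_raw, tb$p_raw, tolerance = 1e-12)
  expect_equal(ta$statistic, -tb$statistic, tolerance = 1e-12)
})

test_that("exact Wilcoxon branch reproduces hand-enumerated p-values", {
  # {1,2,3} vs {4,5,6}: U = 0, two-sided p = 2/20
  norm <- norm_two_groups(c(1, 2, 3), c(4, 5, 6))
  labels <- labels_ab(3, 3)
  w <- wilcoxon_one_vs_rest(norm, labels, "A")
  expect_equal(w$statistic, 0)
  expect_equal(w$p_raw, 0.1, tolerance = 1e-12)

  # {1,2} vs {3}: two-sided p = 2/3
  norm2 <- norm_two_groups(c(1, 2), 3)
  w2 <- wilcoxon_one_vs_rest(norm2, labels_ab(2, 1), "A")
  expect_equal(w2$p_raw, 2 / 3, tolerance = 1e-12)
})

test_that("identical value multisets in both groups give p near 1", {
  norm <- norm_two_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  labels <- labels_ab(4, 4)
  w <- wilcoxon_one_vs_rest(norm, labels, "A")
  expect_gte(w$p_raw, 0.9)
  # fully constant gene: tie-corrected variance collapses, p defined as 1
  normc <- norm_two_groups(rep(2, 4), rep(2, 4))
  expect_equal(wilcoxon_one_vs_rest(normc, labels, "A")$p_raw, 1)
})

test_that("exact Wilcoxon equals permutation enumeration on random instances", {
  set.seed(101)
  for (i in 1:50) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    vals <- sample(seq_len(50), n1 + n2)  # distinct values: no ties
    a <- vals[seq_len(n1)]
    b <- vals[-seq_len(n1)]
    norm <- norm_two_groups(a, b)
    w <- wilcoxon_one_vs_rest(norm, labels_ab(n1, n2), "A")
    expect_equal(w$p_raw, exact_wilcoxon_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon approximation agrees with the stats package", {
  set.seed(5)
  a <- round(rexp(30), 1)  # rounding forces ties
  b <- round(rexp(40) * 1.4, 1)
  norm <- norm_two_groups(a, b)
  w <- wilcoxon_one_vs_rest(norm, labels_ab(30, 40), "A")
  ref <- suppressWarnings(wilcox.test(a, b, correct = TRUE, exact = FALSE))
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(w$p_raw, ref$p.value, tolerance = 1e-9)
})

test_that("Welch t-test matches the hand computation and t.test", {
  norm <- norm_two_groups(c(1, 2, 3), c(2, 3, 4))
  labels <- labels_ab(3, 3)
  tt <- ttest_one_vs_rest(norm, labels, "A")
  expect_equal(tt$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(tt$p_raw, 0.2878641, tolerance = 1e-3)
  ref <- t.test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$p_raw, ref$p.value, tolerance = 1e-9)
  expect_equal(unname(ref$parameter), 4, tolerance = 1e-9)
})

test_that("constant opposite groups stay testable through the variance floor", {
  norm <- norm_two_groups(rep(0, 4), rep(5, 4))
  tt <- ttest_one_vs_rest(norm, labels_ab(4, 4), "A")
  expect_lt(tt$p_raw, 1e-3)

  # a group of size 1 degenerates to p = 1 with a warning
  normd <- norm_two_groups(1, c(2, 3))
  expect_warning(td <- ttest_one_vs_rest(normd, labels_ab(1, 2), "A"),
                 "fewer than 2")
  expect_equal(td$p_raw, 1)
})

test_that("null data give near-zero t statistics", {
  set.seed(13)
  norm <- matrix(rnorm(2 * 400, mean = 5), 2, 400,
                 dimnames = list(c("g1", "g2"), sprintf("c%03d", 1:400)))
  labels <- tibble::tibble(cell_id = colnames(norm),
                           cluster = factor(rep(c("A", "B"), 200)))
  tt <- ttest_one_vs_rest(norm, labels, "A")
  expect_true(all(abs(tt$statistic) < 3))
})

test_that("BH adjustment reproduces the step-up hand example and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone envelope
})

test_that("de_all_clusters returns one adjusted record per cluster-gene pair", {
  set.seed(21)
  sim <- simulate_counts(n_genes = 100, n_cells = 90, n_clusters = 3,
                         markers_per_cluster = 4, seed = 5)
  norm <- log_normalize(filter_genes(sim$counts))
  de <- de_all_clusters(norm, sim$labels, method = "wilcoxon")
  expect_identical(nrow(de), 3L * nrow(norm))
  expect_false(any(duplicated(de[, c("cluster", "gene")])))
  expect_true(all(de$p_adj >= de$p_raw - 1e-12))
  expect_true(all(de$p_adj <= 1 + 1e-12))
  expect_true(all(is.finite(de$lfc)))

  # planted markers should top the signed fold changes of their own cluster
  for (cl in unique(sim$truth$cluster)) {
    planted <- sim$truth$gene[sim$truth$cluster == cl & sim$truth$planted]
    planted <- intersect(planted, rownames(norm))
    sub <- de[de$cluster == cl, ]
    top <- sub$gene[order(-sub$lfc)][seq_along(planted)]
    expect_gte(length(intersect(top, planted)) / length(planted), 0.75)
  }
})
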