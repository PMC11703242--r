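# DE tibble builder: one |lfc| (DE factor) per (cluster, gene)
de_from_factors <- function(factors) {
  # factors: clusters x genes matrix of |lfc| values
  tidyr::expand_grid(cluster = rownames(factors), gene = colnames(factors)) |>
    dplyr::mutate(lfc = purrr::map2_dbl(cluster, gene, ~ factors[.x, .y]),
                  p_raw = 0.01, p_adj = 0.01, statistic = 0, test = "wilcoxon")
}

test_that("marker scores are the log2 ratio of target to mean-other DE factors", {
  factors <- matrix(c(3, 1, 0.5, 1.5), 4, 1,
                    dimnames = list(c("T", "o1", "o2", "o3"), "g1"))
  de <- de_from_factors(factors)
  ms <- marker_scores(de, "T")
  expect_equal(ms$marker_score, log2(3), tolerance = 1e-6)

  # equal DE factor everywhere gives score 0
  de_eq <- de_from_factors(matrix(2, 3, 1, dimnames = list(c("T", "o1", "o2"), "g1")))
  expect_equal(marker_scores(de_eq, "T")$marker_score, 0, tolerance = 1e-12)

  # zero target DE factor with mean others 2 is strongly negative (~ -30.9)
  de0 <- de_from_factors(matrix(c(0, 2, 2), 3, 1,
                                dimnames = list(c("T", "o1", "o2"), "g1")))
  expect_equal(marker_scores(de0, "T")$marker_score,
               log2(1e-9 / (2 + 1e-9)), tolerance = 1e-6)
  expect_lt(marker_scores(de0, "T")$marker_score, -30)
})

test_that("marker scores ignore other-cluster order and increase in the target factor", {
  set.seed(9)
  factors <- matrix(runif(5 * 4, 0.1, 3), 5, 4,
                    dimnames = list(c("T", "o1", "o2", "o3", "o4"),
                                    paste0("g", 1:4)))
  ms1 <- marker_scores(de_from_factors(factors), "T")
  shuffled <- factors[c("T", "o3", "o1", "o4", "o2"), , drop = FALSE]
  ms2 <- marker_scores(de_from_factors(shuffled), "T")
  expect_equal(ms1$marker_score, ms2$marker_score, tolerance = 1e-12)

  bigger <- factors
  bigger["T", ] <- bigger["T", ] + 0.5
  ms3 <- marker_scores(de_from_factors(bigger), "T")
  expect_true(all(ms3$marker_score > ms1$marker_score))

  de_two <- de_from_factors(factors[1, , drop = FALSE])
  expect_error(marker_scores(de_two, "T"), "at least 2 clusters")
})

test_that("candidate pools filter by significance and rank by fold change", {
  de <- tibble::tibble(
    cluster = "T",
    gene = paste0("g", 1:5),
    lfc = c(2.0, 5.0, 1.0, 3.0, 4.0),
    p_adj = c(0.001, 0.2, 0.001, 0.001, 0.001),
    p_raw = p_adj, statistic = 0, test = "wilcoxon"
  )
  pool <- candidate_pool(de, "T", n_pool = 10, alpha = 0.05)
  expect_identical(pool$gene, c("g5", "g4", "g1", "g3"))  # significant, by lfc

  pool2 <- candidate_pool(de, "T", n_pool = 2, alpha = 0.5)
  expect_identical(pool2$gene, c("g2", "g5"))  # truncation to top-2 by lfc

  de_ns <- dplyr::mutate(de, p_adj = 0.9)
  expect_warning(pool3 <- candidate_pool(de_ns, "T", n_pool = 3), "falling back")
  expect_identical(pool3$gene, c("g2", "g5", "g4"))
  expect_true(attr(pool3, "selection_basis")$fallback)

  expect_error(candidate_pool(de, "missing"), "absent")
})

test_that("cosine similarities behave like cosines", {
  cells <- paste0("c", 1:2)
  norm <- rbind(
    g1 = c(1, 0),
    g2 = c(1, 1),
    g3 = c(2, 0),   # scale of g1
    g4 = c(0, 3),   # disjoint support from g1
    g5 = c(0, 0)    # zero profile
  )
  colnames(norm) <- cells
  sim <- cosine_similarity_matrix(norm, rownames(norm))
  expect_equal(sim["g1", "g3"], 1, tolerance = 1e-12)
  expect_equal(sim["g1", "g4"], 0, tolerance = 1e-12)
  expect_equal(sim["g1", "g2"], 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(sim["g5", "g1"], 0)
  expect_equal(sim["g5", "g5"], 1)
  expect_error(cosine_similarity_matrix(norm, character(0)), "empty")
})

test_that("similarity matrices are symmetric with unit diagonal and [0,1] entries", {
  set.seed(14)
  for (i in 1:10) {
    norm <- matrix(rexp(15 * 8), 15, 8,
                   dimnames = list(sprintf("g%02d", 1:15), sprintf("c%d", 1:8)))
    sim <- cosine_similarity_matrix(norm, rownames(norm))
    expect_equal(sim, t(sim), tolerance = 1e-12)
    expect_equal(unname(diag(sim)), rep(1, 15))
    expect_true(all(sim >= 0 & sim <= 1))
  }
})

test_that("cluster mean profiles equal hand-computed means", {
  norm <- matrix(c(1, 3, 0, 2,
                   4, 0, 2, 2), 2, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  labels <- toy_labels()
  prof <- cluster_mean_profiles(norm, labels, c("g1", "g2"))
  expect_equal(prof["A", "g1"], 2)  # cells (1, 3)
  expect_equal(prof["A", "g2"], 2)
  expect_equal(prof["B", "g1"], 1)
  expect_equal(prof["B", "g2"], 2)

  # all-zero gene gives a zero column
  norm0 <- rbind(norm, g3 = 0)
  prof0 <- cluster_mean_profiles(norm0, labels, "g3")
  expect_true(all(prof0 == 0))
})
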