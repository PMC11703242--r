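# Shared in-code fixtures: tiny matrices and labels built fresh per test run.

toy_counts <- function() {
  m <- matrix(
    c(5L, 0L, 1L, 0L,
      0L, 4L, 0L, 3L,
      2L, 2L, 2L, 2L),
    nrow = 3, byrow = TRUE,
    dimnames = list(paste0("g", 1:3), paste0("c", 1:4))
  )
  m
}

toy_labels <- function(cells = paste0("c", 1:4),
                       clusters = c("A", "A", "B", "B")) {
  tibble::tibble(cell_id = cells, cluster = factor(clusters))
}

# Expression matrix whose expm1 means are chosen directly: each gene is
# constant within a group, so group means of expm1(norm) are exact.
norm_from_group_means <- function(mean_a, mean_b, n_a = 3, n_b = 3) {
  stopifnot(length(mean_a) == length(mean_b))
  genes <- sprintf("g%02d", seq_along(mean_a))
  cells <- sprintf("c%02d", seq_len(n_a + n_b))
  m <- cbind(
    matrix(rep(log1p(mean_a), n_a), ncol = n_a),
    matrix(rep(log1p(mean_b), n_b), ncol = n_b)
  )
  dimnames(m) <- list(genes, cells)
  m
}

labels_ab <- function(n_a = 3, n_b = 3) {
  tibble::tibble(
    cell_id = sprintf("c%02d", seq_len(n_a + n_b)),
    cluster = factor(rep(c("A", "B"), c(n_a, n_b)))
  )
}

# Expression matrix with arbitrary per-cell values for two groups.
norm_two_groups <- function(vals_a, vals_b) {
  n_a <- length(vals_a)
  m <- matrix(c(vals_a, vals_b), nrow = 1,
              dimnames = list("g1", sprintf("c%02d", seq_len(n_a + length(vals_b)))))
  m
}

# Random symmetric similarity matrix with unit diagonal, entries in [0, 1].
random_sim <- function(n) {
  s <- matrix(runif(n * n), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

# Independent permutation oracle for the exact two-sided Mann-Whitney p-value:
# enumerate every assignment of the pooled values to a group of size n1 and
# count assignments at least as extreme (|U - n1*n2/2| >= observed).
exact_wilcoxon_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
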