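#' One-vs-rest log2 fold changes
#'
#' For one cluster, computes per-gene
#' `log2((mean expm1(norm) inside + eps) / (mean expm1(norm) outside + eps))`
#' with pseudocount `eps = 1e-9`, i.e. fold changes on the library-size-
#' normalized (de-logged) scale.
#'
#' @param norm Log-normalized genes x cells matrix (see [log_normalize()]).
#' @param labels Tibble with `cell_id`, `cluster` covering every cell.
#' @param cluster Target cluster label.
#' @return Named numeric vector of log2 fold changes, one per gene.
#' @export
log2_fold_change <- function(norm, labels, cluster) {
  cl <- align_labels(norm, labels)
  grp <- split_groups(cl, cluster)
  expr <- expm1(norm)
  lfc_from_means(rowMeans(expr[, grp$in_idx, drop = FALSE]),
                 rowMeans(expr[, grp$out_idx, drop = FALSE]))
}

lfc_from_means <- function(mean_in, mean_out) {
  log2((mean_in + MC_EPS) / (mean_out + MC_EPS))
}

split_groups <- function(cl, cluster) {
  if (!as.character(cluster) %in% levels(cl)) {
    stop("unknown cluster label: ", cluster, call. = FALSE)
  }
  in_idx <- which(cl == as.character(cluster))
  out_idx <- which(cl != as.character(cluster))
  if (length(in_idx) == 0 || length(out_idx) == 0) {
    stop("one-vs-rest comparison needs a non-empty cluster and complement",
         call. = FALSE)
  }
  list(in_idx = in_idx, out_idx = out_idx)
}

#' One-vs-rest Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test of each gene between the target cluster and all
#' remaining cells. When `min(n1, n2) <= 8` and a gene has no tied values the
#' exact null distribution is used; otherwise a tie-corrected normal
#' approximation with continuity correction.
#'
#' @inheritParams log2_fold_change
#' @return Tibble with columns `gene`, `statistic` (U for the target group)
#'   and `p_raw`.
#' @export
wilcoxon_one_vs_rest <- function(norm, labels, cluster) {
  cl <- align_labels(norm, labels)
  grp <- split_groups(cl, cluster)
  n1 <- length(grp$in_idx)
  n2 <- length(grp$out_idx)
  n <- n1 + n2
  exact_ok <- min(n1, n2) <= 8
  mu <- n1 * n2 / 2

  stat <- p <- numeric(nrow(norm))
  for (g in seq_len(nrow(norm))) {
    v <- norm[g, ]
    r <- rank(v)
    u <- sum(r[grp$in_idx]) - n1 * (n1 + 1) / 2
    stat[g] <- u
    tl <- rle(sort(v))$lengths
    has_ties <- any(tl > 1)
    if (exact_ok && !has_ties) {
      p[g] <- if (u == mu) 1 else min(1, 2 * stats::pwilcox(min(u, n1 * n2 - u), n1, n2))
    } else {
      ties_term <- sum(tl^3 - tl)
      sigma2 <- (n1 * n2 / 12) * ((n + 1) - ties_term / (n * (n - 1)))
      if (sigma2 <= 0) {
        p[g] <- 1
      } else {
        z <- u - mu
        z <- (z - sign(z) * 0.5) / sqrt(sigma2)
        p[g] <- min(1, 2 * stats::pnorm(-abs(z)))
      }
    }
  }
  tibble::tibble(gene = rownames(norm), statistic = stat, p_raw = p)
}

#' One-vs-rest Welch t-test
#'
#' Two-sided Welch t-test (unequal variances, Welch-Satterthwaite degrees of
#' freedom) of each gene between the target cluster and all remaining cells.
#' Per-group variances are floored at `1e-12` so constant genes do not divide
#' by zero. If either group has fewer than 2 cells, p = 1 for every gene with
#' a warning.
#'
#' @inheritParams log2_fold_change
#' @return Tibble with columns `gene`, `statistic` (t) and `p_raw`.
#' @export
ttest_one_vs_rest <- function(norm, labels, cluster) {
  cl <- align_labels(norm, labels)
  grp <- split_groups(cl, cluster)
  n1 <- length(grp$in_idx)
  n2 <- length(grp$out_idx)
  if (n1 < 2 || n2 < 2) {
    warning("a group has fewer than 2 cells; t-test is degenerate, p set to 1")
    return(tibble::tibble(gene = rownames(norm),
                          statistic = 0, p_raw = 1))
  }
  x1 <- norm[, grp$in_idx, drop = FALSE]
  x2 <- norm[, grp$out_idx, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- pmax(rowSums((x1 - m1)^2) / (n1 - 1), 1e-12)
  v2 <- pmax(rowSums((x2 - m2)^2) / (n2 - 1), 1e-12)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(gene = rownames(norm), statistic = unname(tstat),
                 p_raw = unname(p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (monotone, capped at 1), preserving
#' input order. Thin validation wrapper around `stats::p.adjust`.
#'
#' @param p_raw Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_raw) {
  if (anyNA(p_raw) || any(p_raw < 0 | p_raw > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_raw, method = "BH")
}

#' One-vs-rest differential expression for every cluster
#'
#' Runs the chosen test and fold-change computation for each cluster against
#' all remaining cells, adjusting p-values per cluster across genes.
#'
#' @inheritParams log2_fold_change
#' @param method `"wilcoxon"` (default) or `"ttest"`.
#' @return Tibble with columns `cluster`, `gene`, `lfc`, `statistic`, `p_raw`,
#'   `p_adj`, `test`.
#' @export
de_all_clusters <- function(norm, labels, method = c("wilcoxon", "ttest")) {
  method <- match.arg(method)
  cl <- align_labels(norm, labels)
  expr <- expm1(norm)
  row_tot <- rowSums(expr)
  n_cells <- ncol(norm)

  purrr::map_dfr(levels(cl), function(target) {
    grp <- split_groups(cl, target)
    mean_in <- rowMeans(expr[, grp$in_idx, drop = FALSE])
    # complement mean from cached totals: avoids a second big subset per cluster
    mean_out <- (row_tot - mean_in * length(grp$in_idx)) / length(grp$out_idx)
    lfc <- lfc_from_means(mean_in, mean_out)
    test <- switch(method,
      wilcoxon = wilcoxon_one_vs_rest(norm, labels, target),
      ttest = ttest_one_vs_rest(norm, labels, target)
    )
    tibble::tibble(
      cluster = target,
      gene = rownames(norm),
      lfc = unname(lfc),
      statistic = test$statistic,
      p_raw = test$p_raw,
      p_adj = bh_adjust(test$p_raw),
      test = method
    )
  })
}

#' Write a differential-expression table to TSV
#'
#' @param de Tibble from [de_all_clusters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(
    dplyr::select(de, dplyr::all_of(c("cluster", "gene", "lfc", "p_raw", "p_adj"))),
    path
  )
  invisible(path)
}
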