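#' Per-gene marker scores for a target cluster
#'
#' The DE factor of gene g in cluster c is the absolute one-vs-rest log2 fold
#' change of g in c. The marker score of g for the target cluster is
#' `log2((DE_target + eps) / (mean over other clusters of DE + eps))`,
#' `eps = 1e-9`: large when a gene is strongly differential in the target
#' cluster but not elsewhere. These scores are the coefficients of the
#' objective's differential term (c1).
#'
#' @param de DE tibble from [de_all_clusters()] covering every cluster.
#' @param cluster Target cluster label.
#' @return Tibble with columns `gene`, `de_factor` (target cluster),
#'   `de_factor_other` (mean over the other clusters) and `marker_score`,
#'   in the gene order of `de`.
#' @export
marker_scores <- function(de, cluster) {
  clusters <- unique(as.character(de$cluster))
  if (length(clusters) < 2) {
    stop("marker scores need one-vs-rest results for at least 2 clusters",
         call. = FALSE)
  }
  if (!as.character(cluster) %in% clusters) {
    stop("cluster `", cluster, "` is absent from the DE results", call. = FALSE)
  }
  de |>
    dplyr::mutate(de_abs = abs(.data$lfc),
                  is_target = .data$cluster == as.character(!!cluster)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      de_factor = .data$de_abs[.data$is_target],
      de_factor_other = mean(.data$de_abs[!.data$is_target]),
      .groups = "drop"
    ) |>
    dplyr::mutate(marker_score = log2((.data$de_factor + MC_EPS) /
                                        (.data$de_factor_other + MC_EPS))) |>
    dplyr::arrange(match(.data$gene, unique(de$gene)))
}

#' DE-filtered candidate gene pool
#'
#' Keeps genes with `p_adj <= alpha` in the target cluster, ranks them by
#' descending log2 fold change (ties broken by gene identifier) and truncates
#' to `n_pool`. If fewer than 2 genes are significant, falls back to the top
#' `n_pool` genes by fold change regardless of `alpha`, with a warning. This is
#' the initial differential-expression filtering step the optimizer downselects
#' from.
#'
#' @param de DE tibble from [de_all_clusters()].
#' @param cluster Target cluster label.
#' @param n_pool Maximum pool size (default 50).
#' @param alpha Adjusted-p significance cutoff in (0, 1\] (default 0.05).
#' @return Tibble with columns `gene`, `lfc`, `p_adj`, carrying attributes
#'   `cluster` and `selection_basis`.
#' @export
candidate_pool <- function(de, cluster, n_pool = 50, alpha = 0.05) {
  if (n_pool < 2) stop("`n_pool` must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  rows <- de[as.character(de$cluster) == as.character(cluster), , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("cluster `", cluster, "` is absent from the DE results", call. = FALSE)
  }
  rows <- dplyr::arrange(rows, dplyr::desc(.data$lfc), .data$gene)
  sig <- rows[rows$p_adj <= alpha, , drop = FALSE]
  fallback <- nrow(sig) < 2
  if (fallback) {
    warning("fewer than 2 genes pass p_adj <= ", alpha, " in cluster ",
            cluster, "; falling back to the top-", n_pool,
            " genes by log2 fold change")
    sig <- rows
  }
  pool <- head(sig, n_pool)
  if (nrow(pool) < 2) {
    stop("candidate pool for cluster ", cluster, " has fewer than 2 genes",
         call. = FALSE)
  }
  out <- tibble::as_tibble(pool[, c("gene", "lfc", "p_adj")])
  attr(out, "cluster") <- as.character(cluster)
  attr(out, "selection_basis") <- list(n_pool = n_pool, alpha = alpha,
                                       fallback = fallback)
  out
}

#' Pairwise cosine similarities of gene expression profiles
#'
#' Cosine similarity of the log-normalized per-cell profiles of every gene
#' pair in the pool. Profiles are non-negative, so similarities lie in
#' \[0, 1\]. A gene with an all-zero profile has similarity 0 to every other
#' gene and 1 to itself by convention. These similarities are the coefficients
#' of the objective's redundancy term (c2).
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param genes Character vector of pool genes (rows of `norm`).
#' @return Symmetric numeric matrix with `genes` as dimnames.
#' @export
cosine_similarity_matrix <- function(norm, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("gene pool is empty", call. = FALSE)
  missing <- setdiff(genes, rownames(norm))
  if (length(missing) > 0) {
    stop("pool genes absent from the matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- norm[genes, , drop = FALSE]
  g <- tcrossprod(x)
  nrm <- sqrt(diag(g))
  sim <- g / outer(nrm, nrm)
  zero <- nrm == 0
  sim[zero, ] <- 0
  sim[, zero] <- 0
  diag(sim) <- 1
  sim[] <- pmin(pmax(sim, 0), 1)
  sim
}

#' Per-cluster mean expression profiles
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param labels Tibble with `cell_id`, `cluster`.
#' @param genes Genes to include (rows of the result's columns).
#' @return Numeric matrix, clusters x genes, of mean log-normalized expression.
#' @export
cluster_mean_profiles <- function(norm, labels, genes) {
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(norm))
  if (length(missing) > 0) {
    stop("genes absent from the matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  cl <- align_labels(norm, labels)
  x <- norm[genes, , drop = FALSE]
  out <- matrix(0, nlevels(cl), length(genes),
                dimnames = list(levels(cl), genes))
  for (lev in levels(cl)) {
    out[lev, ] <- rowMeans(x[, cl == lev, drop = FALSE])
  }
  out
}
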