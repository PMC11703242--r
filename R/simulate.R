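#' Simulate clustered counts with planted cluster-specific markers
#'
#' Draws a genes x cells matrix of negative-binomial counts over equal-sized
#' cell clusters. Each cluster owns a disjoint set of planted marker genes
#' upregulated by `2^log2_effect`; a fraction `overlap` of that (log-scale)
#' effect leaks into the next cluster (cluster c's markers leak into cluster
#' `(c mod K) + 1`), producing overlapping clusters as `overlap` grows.
#' Per-cell library-size factors are log-normal. The mean of gene g in a cell
#' of cluster c is `baseline_mean * libfactor(cell) * 2^E(g, c)`.
#'
#' Defaults describe a well-separated benchmark: 5 clusters of 300 cells,
#' 2000 genes, 10 markers per cluster at log2 effect 4, no overlap.
#'
#' @param n_genes,n_cells,n_clusters Problem dimensions.
#' @param markers_per_cluster Planted markers per cluster (disjoint sets).
#' @param log2_effect Planted fold change on the log2 scale.
#' @param overlap Fraction in \[0, 1\] of the marker effect leaked into the
#'   designated neighbor cluster.
#' @param baseline_mean Baseline negative-binomial mean per gene and cell.
#' @param dispersion Negative-binomial overdispersion (`size = 1/dispersion`).
#' @param libsize_sigma Log-normal standard deviation of per-cell library
#'   factors (0 disables library-size variation).
#' @param cluster_sizes Optional integer vector overriding equal cluster
#'   sizes; must sum to `n_cells`, each entry >= 10.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `counts` (integer matrix), `labels` (tibble: `cell_id`,
#'   `cluster`), `truth` (tibble: `cluster`, `gene`, `log2_effect`, `planted`;
#'   leaked effects carry `planted = FALSE`), and `config`.
#' @export
simulate_counts <- function(n_genes = 2000, n_cells = 1500, n_clusters = 5,
                            markers_per_cluster = 10, log2_effect = 4,
                            overlap = 0, baseline_mean = 0.5, dispersion = 0.4,
                            libsize_sigma = 0.25, cluster_sizes = NULL,
                            seed = 1L) {
  if (n_clusters * markers_per_cluster > n_genes) {
    stop("n_clusters * markers_per_cluster must not exceed n_genes", call. = FALSE)
  }
  if (overlap < 0 || overlap > 1) stop("`overlap` must be in [0, 1]", call. = FALSE)
  if (baseline_mean <= 0 || dispersion <= 0 || log2_effect < 0 ||
      libsize_sigma < 0) {
    stop("count-model parameters out of range", call. = FALSE)
  }
  if (is.null(cluster_sizes)) {
    base <- n_cells %/% n_clusters
    cluster_sizes <- rep(base, n_clusters)
    rem <- n_cells - base * n_clusters
    if (rem > 0) cluster_sizes[seq_len(rem)] <- cluster_sizes[seq_len(rem)] + 1L
  }
  if (length(cluster_sizes) != n_clusters || sum(cluster_sizes) != n_cells) {
    stop("`cluster_sizes` must have one entry per cluster and sum to n_cells",
         call. = FALSE)
  }
  if (any(cluster_sizes < 10)) {
    stop("every cluster must have at least 10 cells", call. = FALSE)
  }

  set.seed(seed)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  cluster_ids <- sprintf("C%d", seq_len(n_clusters))
  cl_of_cell <- rep(seq_len(n_clusters), times = cluster_sizes)

  marker_idx <- sample.int(n_genes, n_clusters * markers_per_cluster)
  markers <- split(marker_idx,
                   rep(seq_len(n_clusters), each = markers_per_cluster))

  # log2-effect matrix, clusters x genes
  effects <- matrix(0, n_clusters, n_genes)
  for (c in seq_len(n_clusters)) {
    effects[c, markers[[c]]] <- log2_effect
    neighbor <- (c %% n_clusters) + 1
    effects[neighbor, markers[[c]]] <-
      effects[neighbor, markers[[c]]] + overlap * log2_effect
  }

  libf <- if (libsize_sigma > 0) {
    stats::rlnorm(n_cells, meanlog = 0, sdlog = libsize_sigma)
  } else {
    rep(1, n_cells)
  }
  mu <- baseline_mean * t(2^effects)[, cl_of_cell, drop = FALSE] *
    matrix(libf, n_genes, n_cells, byrow = TRUE)
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
    n_genes, n_cells, dimnames = list(gene_ids, cell_ids)
  )
  storage.mode(counts) <- "integer"

  truth <- purrr::map_dfr(seq_len(n_clusters), function(c) {
    neighbor <- (c %% n_clusters) + 1
    planted <- tibble::tibble(
      cluster = cluster_ids[c], gene = gene_ids[markers[[c]]],
      log2_effect = log2_effect, planted = TRUE
    )
    if (overlap > 0) {
      leaked <- tibble::tibble(
        cluster = cluster_ids[neighbor], gene = gene_ids[markers[[c]]],
        log2_effect = overlap * log2_effect, planted = FALSE
      )
      dplyr::bind_rows(planted, leaked)
    } else {
      planted
    }
  })

  list(
    counts = counts,
    labels = tibble::tibble(cell_id = cell_ids,
                            cluster = factor(cluster_ids[cl_of_cell],
                                             levels = cluster_ids)),
    truth = truth,
    config = list(
      n_genes = n_genes, n_cells = n_cells, n_clusters = n_clusters,
      markers_per_cluster = markers_per_cluster, log2_effect = log2_effect,
      overlap = overlap, baseline_mean = baseline_mean,
      dispersion = dispersion, libsize_sigma = libsize_sigma,
      cluster_sizes = cluster_sizes, seed = seed
    )
  )
}

#' Precision and recall of a selection against planted markers
#'
#' @param selected Non-empty character vector of selected genes.
#' @param truth Truth tibble from [simulate_counts()].
#' @param cluster Cluster whose planted markers are the reference set.
#' @return One-row tibble: `cluster`, `n_selected`, `n_planted`, `n_hit`,
#'   `precision`, `recall`.
#' @export
recovery_metrics <- function(selected, truth, cluster) {
  if (length(selected) == 0) stop("the selection is empty", call. = FALSE)
  planted <- truth$gene[truth$cluster == as.character(cluster) & truth$planted]
  if (length(planted) == 0) {
    stop("no planted markers recorded for cluster ", cluster, call. = FALSE)
  }
  hit <- length(intersect(selected, planted))
  tibble::tibble(
    cluster = as.character(cluster),
    n_selected = length(selected),
    n_planted = length(planted),
    n_hit = hit,
    precision = hit / length(selected),
    recall = hit / length(planted)
  )
}

#' Write a simulated dataset to disk
#'
#' Emits the counts in Matrix Market form (`counts.mtx` + `genes.txt` +
#' `cells.txt`) and/or as a dense TSV (`counts.tsv`), plus `metadata.tsv`
#' (cell_id, cluster) and `truth.tsv` (cluster, gene, log2_effect, planted).
#'
#' @param sim A [simulate_counts()] result.
#' @param dir Output directory (created if missing).
#' @param format `"both"` (default), `"mtx"`, or `"dense"`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, format = c("both", "mtx", "dense")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format %in% c("both", "mtx")) {
    Matrix::writeMM(Matrix::Matrix(sim$counts, sparse = TRUE),
                    file.path(dir, "counts.mtx"))
    writeLines(rownames(sim$counts), file.path(dir, "genes.txt"))
    writeLines(colnames(sim$counts), file.path(dir, "cells.txt"))
  }
  if (format %in% c("both", "dense")) {
    dense <- tibble::as_tibble(sim$counts, rownames = "gene")
    readr::write_tsv(dense, file.path(dir, "counts.tsv"))
  }
  readr::write_tsv(sim$labels, file.path(dir, "metadata.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
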