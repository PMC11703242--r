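#' Log-ratio difference of selected markers
#'
#' For each selected gene, the log2 ratio of its mean library-size-normalized
#' expression inside the target cluster to the mean outside (pseudocount
#' `1e-9`), plus the median across the selected genes. Higher is better: a
#' strong marker is highly expressed in its cluster and low elsewhere.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param labels Tibble with `cell_id`, `cluster`.
#' @param cluster Target cluster label.
#' @param genes Non-empty character vector of selected genes.
#' @return List with `per_gene` (tibble: `gene`, `log_ratio`) and `median`.
#' @export
log_ratio_difference <- function(norm, labels, cluster, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("the selected gene set is empty", call. = FALSE)
  lfc <- log2_fold_change(norm[genes, , drop = FALSE], labels, cluster)
  list(
    per_gene = tibble::tibble(gene = genes, log_ratio = unname(lfc)),
    median = stats::median(lfc)
  )
}

cosine_vec <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Median cosine similarity of cluster mean profiles
#'
#' Builds, per cluster, the vector of mean log-normalized expression of the
#' selected genes, then returns the median cosine similarity between the
#' target cluster's vector and each other cluster's. Lower is better: markers
#' confined to the target cluster give 0.
#'
#' @inheritParams log_ratio_difference
#' @return A single number in \[0, 1\].
#' @export
median_cosine_metric <- function(norm, labels, cluster, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("the selected gene set is empty", call. = FALSE)
  profiles <- cluster_mean_profiles(norm, labels, genes)
  if (nrow(profiles) < 2) stop("at least two clusters are required", call. = FALSE)
  if (!as.character(cluster) %in% rownames(profiles)) {
    stop("unknown cluster label: ", cluster, call. = FALSE)
  }
  target <- profiles[as.character(cluster), ]
  others <- setdiff(rownames(profiles), as.character(cluster))
  stats::median(vapply(others, function(o) cosine_vec(target, profiles[o, ]),
                       numeric(1)))
}

#' Rank marker-selection methods from per-dataset metric medians
#'
#' Ranks methods within each dataset (rank 1 = best; ties share the mean
#' rank), then reports each method's mean rank across datasets together with
#' the standard deviation of its medians.
#'
#' @param metric_medians Tibble with columns `method`, `dataset`, `median`,
#'   one row per (method, dataset).
#' @param higher_is_better `TRUE` if a larger median is better (log-ratio
#'   metric), `FALSE` if smaller is better (cosine metric).
#' @return Tibble with `method`, `mean_rank`, `sd_median`, sorted by
#'   `mean_rank`.
#' @export
rank_methods <- function(metric_medians, higher_is_better = TRUE) {
  required <- c("method", "dataset", "median")
  miss <- setdiff(required, names(metric_medians))
  if (length(miss) > 0) {
    stop("metric table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  methods <- unique(metric_medians$method)
  datasets <- unique(metric_medians$dataset)
  if (length(methods) < 2) stop("at least 2 methods are required", call. = FALSE)
  full <- tidyr::expand_grid(method = methods, dataset = datasets)
  missing_cells <- dplyr::anti_join(full, metric_medians,
                                    by = c("method", "dataset"))
  if (nrow(missing_cells) > 0) {
    stop("missing metric value for (",
         missing_cells$method[1], ", ", missing_cells$dataset[1], ")",
         call. = FALSE)
  }
  metric_medians |>
    dplyr::group_by(.data$dataset) |>
    dplyr::mutate(rank = if (higher_is_better) {
      rank(-.data$median, ties.method = "average")
    } else {
      rank(.data$median, ties.method = "average")
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_rank = mean(.data$rank),
      sd_median = if (dplyr::n() > 1) stats::sd(.data$median) else 0,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_rank)
}

#' Plot method rankings with variability bars
#'
#' Mean rank per method and metric, with error bars showing the standard
#' deviation of the per-dataset medians.
#'
#' @param rankings Tibble binding [rank_methods()] outputs with an added
#'   `metric` column.
#' @return A ggplot object.
#' @export
plot_method_ranking <- function(rankings) {
  stopifnot(all(c("method", "mean_rank", "sd_median") %in% names(rankings)))
  if (!"metric" %in% names(rankings)) rankings$metric <- "metric"
  ggplot2::ggplot(rankings, ggplot2::aes(x = .data$method, y = .data$mean_rank)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rank - .data$sd_median,
                   ymax = .data$mean_rank + .data$sd_median),
      width = 0.2
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "mean rank (1 = best)") +
    ggplot2::theme_minimal()
}

#' Heatmap of cluster mean expression for a gene set
#'
#' The per-cluster mean log-normalized expression of each gene, the standard
#' visual check that selected markers light up their own cluster only.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param labels Tibble with `cell_id`, `cluster`.
#' @param genes Genes to display.
#' @return A ggplot object.
#' @export
plot_marker_heatmap <- function(norm, labels, genes) {
  profiles <- cluster_mean_profiles(norm, labels, genes)
  df <- tibble::as_tibble(profiles, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "gene", values_to = "mean_expr") |>
    dplyr::mutate(gene = factor(.data$gene, levels = genes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$cluster,
                                   fill = .data$mean_expr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean\nlog-norm") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
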