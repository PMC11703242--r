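#' Select marker genes for one or more clusters
#'
#' Runs the full pipeline on a count matrix and cluster assignments: filter
#' lowly expressed genes, log-normalize, compute one-vs-rest differential
#' expression for every cluster (needed by all marker scores), then per target
#' cluster build the DE-filtered candidate pool and cosine-similarity matrix
#' and optimize the selection objective by stochastic hill climbing.
#'
#' @param counts Genes x cells count matrix (see [read_counts()]).
#' @param labels Tibble with `cell_id`, `cluster`.
#' @param clusters `"all"` (default) or a vector of target cluster labels.
#' @param de_method `"wilcoxon"` or `"ttest"`.
#' @param min_cells,target_sum Preprocessing knobs; see [filter_genes()] and
#'   [log_normalize()].
#' @param n_pool,alpha Candidate-pool knobs; see [candidate_pool()].
#' @param n_markers Fixed marker count per cluster; supplying it enables
#'   constrained mode. `NULL` (default) for unconstrained selection.
#' @param lambda1,lambda2,lambda3 Objective weights; see [objective_config()].
#' @param control An [optimizer_control()].
#' @param seed Integer base seed. Target cluster i uses `seed + 10000 * i` for
#'   its optimizer run, keeping clusters independent but reproducible.
#' @param verbose Log per-cluster progress to standard error.
#' @return An object of class `marker_run`: list with `markers` (tibble over
#'   all pool genes: `cluster, gene, selected, marker_score, log2fc, p_adj,
#'   rank, objective`), `fits` (named list of [hill_climb()] objects), `de`
#'   (full DE tibble), and `params`.
#' @export
select_markers <- function(counts, labels, clusters = "all",
                           de_method = c("wilcoxon", "ttest"),
                           min_cells = 3, target_sum = 1e4,
                           n_pool = 50, alpha = 0.05, n_markers = NULL,
                           lambda1 = 0.9, lambda2 = 0.1, lambda3 = NULL,
                           control = optimizer_control(), seed = 1L,
                           verbose = FALSE) {
  de_method <- match.arg(de_method)
  say <- function(...) if (verbose) message(...)

  counts <- filter_genes(counts, min_cells = min_cells)
  norm <- log_normalize(counts, target_sum = target_sum)
  cl <- align_labels(norm, labels)
  targets <- if (identical(clusters, "all")) levels(cl) else as.character(clusters)
  unknown <- setdiff(targets, levels(cl))
  if (length(unknown) > 0) {
    stop("unknown target cluster(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  say("computing one-vs-rest DE (", de_method, ") for ", nlevels(cl), " clusters")
  de <- de_all_clusters(norm, labels, method = de_method)

  fits <- list()
  marker_rows <- list()
  for (i in seq_along(targets)) {
    target <- targets[i]
    scores_tbl <- marker_scores(de, target)
    pool <- candidate_pool(de, target, n_pool = n_pool, alpha = alpha)
    s <- setNames(scores_tbl$marker_score, scores_tbl$gene)[pool$gene]
    sim <- cosine_similarity_matrix(norm, pool$gene)
    config <- objective_config(lambda1 = lambda1, lambda2 = lambda2,
                               lambda3 = lambda3, k = n_markers)
    fit <- hill_climb(s, sim, config = config, control = control,
                      seed = seed + 10000L * i)
    say("cluster ", target, ": pool ", nrow(pool), ", selected ",
        sum(fit$x), ", objective ", format(fit$objective, digits = 6))
    fits[[target]] <- fit

    tbl <- tibble::tibble(
      cluster = target,
      gene = pool$gene,
      selected = fit$x == 1,
      marker_score = unname(s),
      log2fc = pool$lfc,
      p_adj = pool$p_adj,
      objective = fit$objective
    )
    tbl <- dplyr::arrange(tbl, dplyr::desc(.data$marker_score))
    tbl$rank <- NA_integer_
    tbl$rank[tbl$selected] <- seq_len(sum(tbl$selected))
    marker_rows[[target]] <- tbl
  }

  structure(
    list(
      markers = dplyr::bind_rows(marker_rows),
      fits = fits,
      de = de,
      params = list(
        clusters = targets, de_method = de_method, min_cells = min_cells,
        target_sum = target_sum, n_pool = n_pool, alpha = alpha,
        n_markers = n_markers, lambda1 = lambda1, lambda2 = lambda2,
        lambda3 = lambda3, control = unclass(control), seed = seed
      )
    ),
    class = "marker_run"
  )
}

#' @export
print.marker_run <- function(x, ...) {
  sel <- dplyr::filter(x$markers, .data$selected)
  cat("Marker selection run: ", length(x$fits), " cluster(s), ",
      nrow(sel), " markers selected\n", sep = "")
  counts <- dplyr::count(sel, .data$cluster)
  for (i in seq_len(nrow(counts))) {
    cat("  ", counts$cluster[i], ": ", counts$n[i], " marker(s)\n", sep = "")
  }
  invisible(x)
}

#' Tidy a marker run into its marker table
#'
#' @param x A `marker_run` object.
#' @param ... Unused.
#' @return The per-(cluster, pool gene) marker tibble.
#' @method tidy marker_run
#' @export
tidy.marker_run <- function(x, ...) {
  x$markers
}

#' Per-cluster summary of a marker run
#'
#' @param x A `marker_run` object.
#' @param ... Unused.
#' @return Tibble with one row per target cluster: `cluster`, `n_pool`,
#'   `n_selected`, `objective`.
#' @method glance marker_run
#' @export
glance.marker_run <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(cl) {
    f <- x$fits[[cl]]
    tibble::tibble(cluster = cl, n_pool = length(f$x),
                   n_selected = sum(f$x), objective = f$objective)
  })
}

#' Run the pipeline from files and write all outputs
#'
#' File-level wrapper around [select_markers()]: reads the counts and
#' metadata, runs the selection, and writes `markers.tsv`, `trace.tsv`,
#' `de.tsv` and a JSON `manifest.json` recording every parameter (including
#' the seed) to the output directory. A run is exactly reproducible from its
#' manifest via [run_from_manifest()].
#'
#' @param counts_path,format,genes_path,cells_path,transpose Input matrix
#'   description; see [read_counts()].
#' @param meta_path,cell_col,cluster_col Metadata description; see
#'   [read_cluster_labels()].
#' @param out_dir Output directory (created if missing).
#' @param ... Further arguments passed to [select_markers()].
#' @return The `marker_run`, invisibly.
#' @export
run_pipeline <- function(counts_path, format = "auto", genes_path = NULL,
                         cells_path = NULL, transpose = FALSE,
                         meta_path, cell_col = "cell_id",
                         cluster_col = "cluster", out_dir, ...) {
  counts <- read_counts(counts_path, format = format, genes = genes_path,
                        cells = cells_path, transpose = transpose)
  labels <- read_cluster_labels(meta_path, cell_col = cell_col,
                                cluster_col = cluster_col)
  run <- select_markers(counts, labels, ...)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_marker_table(run$markers, file.path(out_dir, "markers.tsv"))
  write_de_table(run$de, file.path(out_dir, "de.tsv"))
  trace <- purrr::map_dfr(names(run$fits),
                          function(cl) dplyr::mutate(run$fits[[cl]]$trace,
                                                     cluster = cl,
                                                     .before = 1))
  readr::write_tsv(trace, file.path(out_dir, "trace.tsv"))

  manifest <- c(
    list(counts_path = counts_path, format = format, genes_path = genes_path,
         cells_path = cells_path, transpose = transpose,
         meta_path = meta_path, cell_col = cell_col,
         cluster_col = cluster_col, out_dir = out_dir),
    run$params
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(run)
}

#' Re-run a pipeline from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by [run_pipeline()].
#' @param out_dir Optional override of the manifest's output directory.
#' @return The `marker_run`, invisibly.
#' @export
run_from_manifest <- function(manifest_path, out_dir = NULL) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!is.null(out_dir)) m$out_dir <- out_dir
  control <- do.call(optimizer_control,
                     m$control[setdiff(names(m$control), "neighbors_per_step")])
  if (!is.null(m$control$neighbors_per_step)) {
    control$neighbors_per_step <- m$control$neighbors_per_step
  }
  run_pipeline(
    counts_path = m$counts_path, format = m$format,
    genes_path = m$genes_path, cells_path = m$cells_path,
    transpose = isTRUE(m$transpose),
    meta_path = m$meta_path, cell_col = m$cell_col,
    cluster_col = m$cluster_col, out_dir = m$out_dir,
    clusters = m$clusters, de_method = m$de_method,
    min_cells = m$min_cells, target_sum = m$target_sum,
    n_pool = m$n_pool, alpha = m$alpha, n_markers = m$n_markers,
    lambda1 = m$lambda1, lambda2 = m$lambda2, lambda3 = m$lambda3,
    control = control, seed = m$seed
  )
}
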