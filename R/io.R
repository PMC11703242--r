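#' Read a genes-by-cells count matrix
#'
#' Reads raw counts from either a Matrix Market triplet file with one-name-per-
#' line gene and cell sidecar files, or a dense delimited table (gene ids in the
#' first column, cell ids in the header). The returned matrix is always
#' genes x cells; set `transpose = TRUE` when the file is stored cells x genes,
#' as many exporters do.
#'
#' @param path Path to the matrix file (`.mtx` or a delimited table).
#' @param format `"mtx"`, `"dense"`, or `"auto"` (decide from the extension).
#' @param genes,cells Sidecar files naming rows/columns; required for `"mtx"`.
#'   Multi-column sidecars (e.g. 10x `features.tsv`) use the first field.
#' @param transpose If `TRUE`, the on-disk orientation is cells x genes and the
#'   matrix is transposed after reading.
#' @return An integer matrix, genes in rows, cells in columns, with unique
#'   dimnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tc1\tc2", "g1\t0\t3", "g2\t5\t1"), tf)
#' read_counts(tf)
#' @export
read_counts <- function(path, format = c("auto", "mtx", "dense"),
                        genes = NULL, cells = NULL, transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("count matrix file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "mtx") {
    if (is.null(genes) || is.null(cells)) {
      stop("matrix-market input requires `genes` and `cells` sidecar files",
           call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- sub("[\t,].*$", "", readLines(genes))
    cell_ids <- sub("[\t,].*$", "", readLines(cells))
    if (transpose) m <- t(m)
    if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids)) {
      stop(sprintf(
        "matrix is %d x %d after orientation but sidecars name %d genes and %d cells",
        nrow(m), ncol(m), length(gene_ids), length(cell_ids)
      ), call. = FALSE)
    }
    dimnames(m) <- list(gene_ids, cell_ids)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tbl <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                             stringsAsFactors = FALSE, comment.char = "")
    m <- as.matrix(tbl[, -1, drop = FALSE])
    rownames(m) <- as.character(tbl[[1]])
    if (transpose) m <- t(m)
  }
  validate_counts(m)
}

# shared count-matrix contract: unique ids on both axes, non-negative
# integer-valued entries; storage coerced to integer
validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix must carry gene and cell identifiers", call. = FALSE)
  }
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g) > 0) {
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_c <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_c) > 0) {
    stop("duplicate cell identifiers: ", paste(dup_c, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(m)) stop("count matrix contains missing values", call. = FALSE)
  if (any(m < 0)) stop("count matrix contains negative values", call. = FALSE)
  if (length(m) > 0 && max(abs(m - round(m))) > 1e-8) {
    stop("count matrix contains non-integer values", call. = FALSE)
  }
  m <- round(m)
  if (length(m) == 0 || max(m) < .Machine$integer.max) storage.mode(m) <- "integer"
  m
}

#' Read per-cell cluster assignments
#'
#' @param path Delimited metadata table with one row per cell.
#' @param cell_col,cluster_col Column names holding cell identifiers and
#'   cluster labels.
#' @return A tibble with columns `cell_id` and `cluster` (factor).
#' @export
read_cluster_labels <- function(path, cell_col = "cell_id",
                                cluster_col = "cluster") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  for (col in c(cell_col, cluster_col)) {
    if (!col %in% names(tbl)) {
      stop("metadata is missing column `", col, "`", call. = FALSE)
    }
  }
  tibble::tibble(
    cell_id = as.character(tbl[[cell_col]]),
    cluster = factor(tbl[[cluster_col]])
  )
}

# Align a labels tibble to the cell columns of an expression matrix; every
# cell must have exactly one label and at least two clusters must remain.
align_labels <- function(mat, labels) {
  stopifnot(is.data.frame(labels), all(c("cell_id", "cluster") %in% names(labels)))
  if (anyDuplicated(labels$cell_id) > 0) {
    stop("metadata assigns more than one cluster to some cells", call. = FALSE)
  }
  idx <- match(colnames(mat), labels$cell_id)
  if (anyNA(idx)) {
    missing <- colnames(mat)[is.na(idx)]
    stop("cells without a cluster label: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  }
  cl <- factor(as.character(labels$cluster[idx]))
  if (nlevels(cl) < 2) {
    stop("at least two distinct clusters are required", call. = FALSE)
  }
  cl
}

#' Filter lowly expressed genes
#'
#' Keeps genes detected (nonzero count) in at least `min_cells` cells; the cell
#' axis and the order of surviving genes are unchanged.
#'
#' @param counts Genes x cells count matrix.
#' @param min_cells Minimum number of cells with a nonzero count.
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, min_cells = 3) {
  stopifnot(is.matrix(counts))
  if (min_cells < 1) stop("`min_cells` must be >= 1", call. = FALSE)
  keep <- rowSums(counts > 0) >= min_cells
  if (!any(keep)) {
    stop("no gene is detected in at least ", min_cells,
         " cells; the feature space is empty", call. = FALSE)
  }
  counts[keep, , drop = FALSE]
}

#' Library-size scale and log-transform counts
#'
#' Each cell's counts are scaled to sum to `target_sum` and transformed with
#' the natural-log `log1p`: entry (g, c) becomes
#' `log(1 + count * target_sum / total(c))`. Cells with zero total counts are
#' dropped with a warning.
#'
#' @param counts Genes x cells count matrix.
#' @param target_sum Per-cell total after scaling (default `1e4`).
#' @return A numeric genes x cells matrix with attribute `target_sum`.
#' @export
log_normalize <- function(counts, target_sum = 1e4) {
  stopifnot(is.matrix(counts))
  if (!is.numeric(target_sum) || length(target_sum) != 1 || target_sum <= 0) {
    stop("`target_sum` must be a positive number", call. = FALSE)
  }
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " cell(s) with zero total counts")
    counts <- counts[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  norm <- log1p(sweep(counts, 2, target_sum / totals, `*`))
  storage.mode(norm) <- "double"
  attr(norm, "target_sum") <- target_sum
  norm
}

#' Write a marker table to TSV
#'
#' Writes the selected markers (rows with `selected == TRUE`) as a
#' tab-separated file with columns
#' `cluster, gene, selected, marker_score, log2fc, p_adj, rank, objective`,
#' ordered by cluster and then by descending marker score. Clusters with an
#' empty selection contribute no rows and trigger a warning.
#'
#' @param markers Marker tibble, e.g. `tidy()` of a [select_markers()] run.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  required <- c("cluster", "gene", "selected", "marker_score", "log2fc", "p_adj")
  miss <- setdiff(required, names(markers))
  if (length(miss) > 0) {
    stop("marker table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"rank" %in% names(markers)) markers$rank <- NA_integer_
  if (!"objective" %in% names(markers)) markers$objective <- NA_real_
  empty <- setdiff(unique(as.character(markers$cluster)),
                   unique(as.character(markers$cluster[markers$selected])))
  if (length(empty) > 0) {
    warning("no selected markers for cluster(s): ", paste(empty, collapse = ", "))
  }
  out <- markers |>
    dplyr::filter(.data$selected) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$marker_score)) |>
    dplyr::select(dplyr::all_of(c(required, "rank", "objective")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read back a marker table written by [write_marker_table()]
#'
#' @param path TSV file path.
#' @return A tibble with one row per selected marker.
#' @export
read_marker_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    cluster = readr::col_character(),
                    gene = readr::col_character(),
                    selected = readr::col_logical()
                  ))
}
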