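#' Objective configuration
#'
#' The selection objective is `F(x) = lambda1 * c1 - lambda2 * c2 - lambda3 * c3`
#' over binary selection vectors x, where c1 is the summed marker score of the
#' selected genes, c2 the pair-normalized redundancy magnitude
#' `2 * sum_{g1<g2} x_g1 x_g2 sim(g1,g2) / (S(S-1) + 1)` with `S = sum(x)`, and
#' c3 the selected count S. Constrained mode fixes S = k throughout the search
#' (swap neighborhood); unconstrained mode lets lambda3 govern the set size.
#'
#' @param lambda1 Weight on the differential marker term (default 0.9).
#' @param lambda2 Weight on the redundancy penalty (default 0.1).
#' @param lambda3 Weight on the sparsity penalty. Defaults to 0.05 in
#'   unconstrained mode and 0 in constrained mode, where the term is constant.
#' @param k Fixed number of markers; supplying it selects constrained mode.
#' @return A list of class `objective_config`.
#' @export
objective_config <- function(lambda1 = 0.9, lambda2 = 0.1, lambda3 = NULL,
                             k = NULL) {
  mode <- if (is.null(k)) "unconstrained" else "constrained"
  if (is.null(lambda3)) lambda3 <- if (mode == "constrained") 0 else 0.05
  if (any(c(lambda1, lambda2, lambda3) < 0)) {
    stop("lambda weights must be non-negative", call. = FALSE)
  }
  if (!is.null(k)) {
    k <- as.integer(k)
    if (is.na(k) || k < 2) stop("`k` must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
         mode = mode, k = k),
    class = "objective_config"
  )
}

check_alignment <- function(x, n, what = "selection vector") {
  if (length(x) != n) {
    stop(what, " has length ", length(x),
         " but the pool has ", n, " genes", call. = FALSE)
  }
  if (!all(x %in% c(0, 1))) stop("selection entries must be 0 or 1", call. = FALSE)
  invisible(TRUE)
}

#' Differential term c1: summed marker score of selected genes
#'
#' @param x Binary selection vector aligned to the pool.
#' @param scores Numeric marker scores aligned to the pool.
#' @return `sum(x * scores)`.
#' @export
objective_c1 <- function(x, scores) {
  check_alignment(x, length(scores))
  sum(scores[x == 1])
}

#' Redundancy term c2: pair-normalized cosine similarity of selected genes
#'
#' Returns the non-negative magnitude
#' `2 * sum_{g1<g2} x_g1 x_g2 sim(g1,g2) / (S(S-1) + 1)`; the objective
#' subtracts `lambda2` times this value. Zero when fewer than two genes are
#' selected.
#'
#' @param x Binary selection vector aligned to the pool.
#' @param sim Symmetric similarity matrix over the pool.
#' @return The redundancy magnitude.
#' @export
objective_c2 <- function(x, sim) {
  check_alignment(x, nrow(sim))
  s <- sum(x)
  if (s < 2) return(0)
  sub <- sim[x == 1, x == 1, drop = FALSE]
  (sum(sub) - sum(diag(sub))) / (s * (s - 1) + 1)
}

#' Sparsity term c3: number of selected genes
#'
#' @param x Binary selection vector.
#' @return `sum(x)`; the objective subtracts `lambda3` times this value.
#' @export
objective_c3 <- function(x) {
  sum(x)
}

#' Evaluate the full selection objective
#'
#' @param x Binary selection vector aligned to the pool.
#' @param scores Marker scores aligned to the pool.
#' @param sim Similarity matrix over the pool.
#' @param config An [objective_config()].
#' @return `lambda1*c1 - lambda2*c2 - lambda3*c3`.
#' @export
evaluate_objective <- function(x, scores, sim, config = objective_config()) {
  check_alignment(x, length(scores))
  config$lambda1 * objective_c1(x, scores) -
    config$lambda2 * objective_c2(x, sim) -
    config$lambda3 * objective_c3(x)
}

#' Unconstrained neighborhood: bit flips
#'
#' Generates up to `n_neighbors` neighbors by flipping between 1 and `n_flips`
#' distinct positions. When the pool is no larger than `n_neighbors`, all
#' single-flip neighbors are enumerated (in position order) and any remaining
#' slots are filled with random multi-flip states.
#'
#' @param x Binary selection vector.
#' @param n_flips Maximum positions flipped per neighbor (>= 1).
#' @param n_neighbors Number of neighbors to generate.
#' @return List of binary vectors, each differing from `x` in >= 1 position.
#' @export
neighbors_unconstrained <- function(x, n_flips = 2, n_neighbors = length(x)) {
  n <- length(x)
  stopifnot(n_flips >= 1, n_neighbors >= 1)
  nb <- list()
  if (n <= n_neighbors) {
    nb <- lapply(seq_len(n), function(j) {
      y <- x
      y[j] <- 1 - y[j]
      y
    })
  }
  extra <- n_neighbors - length(nb)
  if (extra > 0 && (n_flips > 1 || length(nb) == 0)) {
    for (i in seq_len(extra)) {
      m <- if (n_flips == 1) 1 else sample.int(min(n_flips, n), 1)
      j <- sample.int(n, m)
      y <- x
      y[j] <- 1 - y[j]
      nb[[length(nb) + 1]] <- y
    }
  }
  nb
}

#' Constrained neighborhood: swaps preserving the selected count
#'
#' Each neighbor sets one selected position to 0 and one unselected position
#' to 1, so `sum(x)` is preserved exactly. All swaps are enumerated when there
#' are at most `n_neighbors` of them; otherwise `n_neighbors` random swaps are
#' drawn.
#'
#' @param x Binary selection vector with `0 < sum(x) < length(x)`.
#' @param n_neighbors Number of neighbors to generate.
#' @return List of binary vectors with the same selected count as `x`.
#' @export
neighbors_constrained <- function(x, n_neighbors = length(x)) {
  ones <- which(x == 1)
  zeros <- which(x == 0)
  if (length(ones) == 0 || length(zeros) == 0) {
    stop("constrained neighborhood is empty: k must satisfy 0 < k < pool size",
         call. = FALSE)
  }
  swap <- function(i, j) {
    y <- x
    y[i] <- 0
    y[j] <- 1
    y
  }
  n_total <- length(ones) * length(zeros)
  if (n_total <= n_neighbors) {
    nb <- vector("list", n_total)
    idx <- 1
    for (i in ones) {
      for (j in zeros) {
        nb[[idx]] <- swap(i, j)
        idx <- idx + 1
      }
    }
    nb
  } else {
    lapply(seq_len(n_neighbors), function(dummy) {
      swap(ones[sample.int(length(ones), 1)], zeros[sample.int(length(zeros), 1)])
    })
  }
}

#' Exhaustive optimum of the selection objective
#'
#' Enumerates every admissible selection vector (all 2^n in unconstrained
#' mode, all size-k subsets in constrained mode) and returns the maximizer,
#' breaking ties toward the lexicographically smallest vector. Intended as a
#' test oracle for small pools.
#'
#' @param scores Marker scores aligned to the pool (named).
#' @param sim Similarity matrix over the pool.
#' @param config An [objective_config()].
#' @return List with `x` (binary vector, named if `scores` is) and `objective`.
#' @export
brute_force_optimum <- function(scores, sim, config = objective_config()) {
  n <- length(scores)
  stopifnot(nrow(sim) == n, ncol(sim) == n)
  if (config$mode == "unconstrained") {
    if (n > 20) {
      stop("pool too large for exhaustive search (n > 20); use hill_climb()",
           call. = FALSE)
    }
    states <- 0:(2^n - 1)
    x_mat <- matrix(0, length(states), n)
    for (j in seq_len(n)) {
      x_mat[, j] <- as.numeric(bitwAnd(states, bitwShiftL(1L, n - j)) > 0)
    }
  } else {
    k <- config$k
    if (k >= n) {
      stop("constrained mode requires k < pool size", call. = FALSE)
    }
    if (choose(n, k) > 1e6) {
      stop("too many subsets for exhaustive search; use hill_climb()",
           call. = FALSE)
    }
    combos <- utils::combn(n, k)
    x_mat <- matrix(0, ncol(combos), n)
    for (i in seq_len(ncol(combos))) x_mat[i, combos[, i]] <- 1
  }
  s_sel <- rowSums(x_mat)
  c1 <- drop(x_mat %*% scores)
  quad <- rowSums((x_mat %*% sim) * x_mat)
  diag_part <- drop(x_mat %*% diag(sim))
  r <- (quad - diag_part) / (s_sel * (s_sel - 1) + 1)
  f <- config$lambda1 * c1 - config$lambda2 * r - config$lambda3 * s_sel
  best_f <- max(f)
  cand <- which(f >= best_f - 1e-12)
  # lexicographically smallest maximizer: order candidate rows column by column
  ord <- do.call(order, as.data.frame(x_mat[cand, , drop = FALSE]))
  x <- x_mat[cand[ord[1]], ]
  names(x) <- names(scores)
  list(x = x, objective = evaluate_objective(x, scores, sim, config))
}
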