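#' Optimizer control parameters
#'
#' @param epsilon0 Initial exploration rate in \[0, 1\]; at iteration t a
#'   uniformly random neighbor is accepted with probability
#'   `epsilon0 * exp(-decay * t)`.
#' @param decay Positive exponential decay constant of the exploration rate.
#' @param patience Iterations without best-ever improvement before stopping.
#' @param max_iters Hard iteration cap per restart.
#' @param neighbors_per_step Neighbors evaluated per greedy step; defaults to
#'   `min(pool size, 20)`.
#' @param restarts Independent random restarts; the best state over all
#'   restarts is returned.
#' @param n_flips Maximum bits flipped per unconstrained neighbor.
#' @return A list of class `optimizer_control`.
#' @export
optimizer_control <- function(epsilon0 = 0.3, decay = 0.01, patience = 50L,
                              max_iters = 1000L, neighbors_per_step = NULL,
                              restarts = 5L, n_flips = 2L) {
  if (epsilon0 < 0 || epsilon0 > 1) stop("`epsilon0` must be in [0, 1]", call. = FALSE)
  if (decay <= 0) stop("`decay` must be positive", call. = FALSE)
  for (v in c(patience = patience, max_iters = max_iters,
              restarts = restarts, n_flips = n_flips)) {
    if (v < 1) stop("control counts must be positive integers", call. = FALSE)
  }
  structure(
    list(epsilon0 = epsilon0, decay = decay, patience = as.integer(patience),
         max_iters = as.integer(max_iters),
         neighbors_per_step = neighbors_per_step,
         restarts = as.integer(restarts), n_flips = as.integer(n_flips)),
    class = "optimizer_control"
  )
}

#' Stochastic hill climbing over binary gene selections
#'
#' Maximizes the three-term selection objective by epsilon-greedy local
#' search. Each restart r seeds the generator with `seed + r` and initializes
#' the selection at random (unconstrained: independent Bernoulli(0.5) bits;
#' constrained: a uniform random k-subset). At iteration t a neighborhood is
#' generated (bit flips, or swaps in constrained mode); with probability
#' `epsilon0 * exp(-decay * t)` a random neighbor is accepted (exploration),
#' otherwise the search moves to the best neighbor if it strictly improves the
#' current objective. The best state ever visited is tracked separately —
#' exploration can worsen the current state but never the reported solution —
#' and a restart stops after `patience` iterations without best-ever
#' improvement, or at `max_iters`.
#'
#' @param scores Named numeric vector of marker scores over the candidate pool.
#' @param sim Symmetric cosine-similarity matrix over the pool.
#' @param config An [objective_config()].
#' @param control An [optimizer_control()].
#' @param seed Integer seed; the run is fully reproducible given it.
#' @return An object of class `hill_climb`: list with `x` (named binary
#'   vector), `genes` (selected gene identifiers), `objective`, `trace`
#'   (tibble: `restart, iter, current, best, n_selected, epsilon`),
#'   `best_restart`, plus the inputs `scores`, `config`, `control`, `seed`.
#' @export
hill_climb <- function(scores, sim, config = objective_config(),
                       control = optimizer_control(), seed = 1L) {
  n <- length(scores)
  if (n < 2) stop("the candidate pool must contain at least 2 genes", call. = FALSE)
  stopifnot(nrow(sim) == n, ncol(sim) == n)
  if (config$mode == "constrained" && (config$k < 2 || config$k > n - 1)) {
    stop("constrained mode requires 2 <= k <= pool size - 1 (got k = ",
         config$k, ", pool = ", n, ")", call. = FALSE)
  }
  n_nb <- control$neighbors_per_step
  if (is.null(n_nb)) n_nb <- min(n, 20L)

  l1 <- config$lambda1
  l2 <- config$lambda2
  l3 <- config$lambda3
  eval_state <- function(x) {
    s <- sum(x)
    c1 <- sum(scores[x == 1])
    r <- 0
    if (s >= 2) {
      sub <- sim[x == 1, x == 1, drop = FALSE]
      r <- (sum(sub) - sum(diag(sub))) / (s * (s - 1) + 1)
    }
    l1 * c1 - l2 * r - l3 * s
  }

  best_x <- NULL
  best_f <- -Inf
  best_restart <- NA_integer_
  tr_restart <- tr_iter <- tr_cur <- tr_best <- tr_size <- tr_eps <- list()

  for (r in seq_len(control$restarts)) {
    set.seed(seed + r)
    x <- if (config$mode == "constrained") {
      y <- rep(0, n)
      y[sample.int(n, config$k)] <- 1
      y
    } else {
      stats::rbinom(n, 1, 0.5)
    }
    cur_f <- eval_state(x)
    run_best_f <- cur_f
    run_best_x <- x
    stall <- 0L
    cur <- bst <- size <- eps_v <- numeric(control$max_iters)
    used <- 0L

    for (t in seq_len(control$max_iters)) {
      eps_t <- control$epsilon0 * exp(-control$decay * t)
      nb <- if (config$mode == "constrained") {
        neighbors_constrained(x, n_neighbors = n_nb)
      } else {
        neighbors_unconstrained(x, n_flips = control$n_flips, n_neighbors = n_nb)
      }
      if (stats::runif(1) < eps_t) {
        x <- nb[[sample.int(length(nb), 1)]]
        cur_f <- eval_state(x)
      } else {
        fs <- vapply(nb, eval_state, numeric(1))
        j <- which.max(fs)
        if (fs[j] > cur_f) {
          x <- nb[[j]]
          cur_f <- fs[j]
        }
      }
      if (config$mode == "constrained" && sum(x) != config$k) {
        stop("internal error: constrained state lost sum(x) = k", call. = FALSE)
      }
      if (cur_f > run_best_f) {
        run_best_f <- cur_f
        run_best_x <- x
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      used <- t
      cur[t] <- cur_f
      bst[t] <- run_best_f
      size[t] <- sum(x)
      eps_v[t] <- eps_t
      if (stall >= control$patience) break
    }

    idx <- seq_len(used)
    tr_restart[[r]] <- rep(r, used)
    tr_iter[[r]] <- idx
    tr_cur[[r]] <- cur[idx]
    tr_best[[r]] <- bst[idx]
    tr_size[[r]] <- size[idx]
    tr_eps[[r]] <- eps_v[idx]

    if (run_best_f > best_f) {
      best_f <- run_best_f
      best_x <- run_best_x
      best_restart <- r
    }
  }

  names(best_x) <- names(scores)
  structure(
    list(
      x = best_x,
      genes = names(scores)[best_x == 1],
      objective = best_f,
      trace = tibble::tibble(
        restart = unlist(tr_restart), iter = unlist(tr_iter),
        current = unlist(tr_cur), best = unlist(tr_best),
        n_selected = unlist(tr_size), epsilon = unlist(tr_eps)
      ),
      best_restart = best_restart,
      scores = scores, config = config, control = control, seed = seed
    ),
    class = "hill_climb"
  )
}

#' @export
print.hill_climb <- function(x, ...) {
  cat("Stochastic hill climb (", x$config$mode, " mode)\n", sep = "")
  cat("  pool size:  ", length(x$x), "\n", sep = "")
  cat("  selected:   ", sum(x$x), " gene(s)\n", sep = "")
  cat("  objective:  ", format(x$objective, digits = 7), "\n", sep = "")
  cat("  restarts:   ", x$control$restarts,
      " (best from restart ", x$best_restart, ")\n", sep = "")
  if (length(x$genes) > 0) {
    cat("  genes: ", paste(head(x$genes, 10), collapse = ", "),
        if (length(x$genes) > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a hill-climb fit into one row per pool gene
#'
#' @param x A `hill_climb` object.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `selected`, `marker_score`.
#' @method tidy hill_climb
#' @export
tidy.hill_climb <- function(x, ...) {
  tibble::tibble(
    gene = names(x$x),
    selected = x$x == 1,
    marker_score = unname(x$scores)
  )
}

#' One-row summary of a hill-climb fit
#'
#' @param x A `hill_climb` object.
#' @param ... Unused.
#' @return Tibble with `objective`, `n_selected`, `n_pool`, `mode`,
#'   `iterations` (total over restarts), `restarts`, `best_restart`.
#' @method glance hill_climb
#' @export
glance.hill_climb <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_selected = sum(x$x),
    n_pool = length(x$x),
    mode = x$config$mode,
    iterations = nrow(x$trace),
    restarts = x$control$restarts,
    best_restart = x$best_restart
  )
}

#' Plot the optimization trace of a hill climb
#'
#' Current and best-ever objective per iteration, one panel per restart.
#'
#' @param object A `hill_climb` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hill_climb
#' @export
autoplot.hill_climb <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("current", "best"),
                            names_to = "series", values_to = "objective")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iter, y = .data$objective,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$restart), labeller = "label_both") +
    ggplot2::labs(x = "iteration", y = "objective", colour = NULL) +
    ggplot2::theme_minimal()
}
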