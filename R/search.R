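#' Learn a decomposable graph by greedy chordality-preserving search
#'
#' Starting from the empty graph, each iteration enumerates every admissible
#' single-edge insertion and deletion (those preserving chordality), scores
#' each by its closed-form four-term local score change, and applies the move
#' with the largest strictly positive change; the search stops at a local
#' optimum where no admissible move improves the score. The bandwidth is
#' selected once, before the search, and held fixed. Chordality is an
#' invariant of every visited state.
#'
#' Ties among equal-change moves are broken by preferring insertion over
#' deletion, then lexicographically by `(i, j)`, so a fixed data matrix and
#' configuration reproduce the identical move sequence.
#'
#' @param X Numeric data matrix or data frame (rows = observations, columns
#'   = variables). All rows are used for estimation; do any train/test
#'   splitting before calling.
#' @param score `"cbic"` (copula-information score with complexity penalty)
#'   or `"ng_ll"` (cross-validated raw-scale kernel log-likelihood, no
#'   penalty).
#' @param config An [estimator_config()].
#' @param penalty Penalty form for `"cbic"`; see [score_config()].
#' @param max_iter Iteration cap; defaults to `d * (d - 1)` (the greedy
#'   strict-improvement rule terminates on its own; the cap guards numerical
#'   cycling).
#' @param debug_checks Re-verify chordality of the current graph at every
#'   iteration.
#' @param verbose Print accepted moves.
#' @return An object of class `decomposable_fit`: the learned `graph` (a
#'   [ug()]), its `tree` (a [clique_tree()]), the per-iteration `trace`
#'   tibble (move, separator size, score change, running global score,
#'   clique statistics), the selected `theta`, and the final `score`.
#' @examples
#' \donttest{
#' sim <- simulate_benchmark(d = 6, n = 400, rho = 0.2, seed = 1)
#' fit <- learn_structure(sim$X$normal)
#' glance(fit)
#' }
#' @export
learn_structure <- function(X, score = c("cbic", "ng_ll"),
                            config = estimator_config(),
                            penalty = c("quadratic", "linear"),
                            max_iter = NULL, debug_checks = FALSE,
                            verbose = FALSE) {
  score <- match.arg(score)
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  n_tr <- nrow(X)
  d <- ncol(X)
  if (is.null(max_iter)) max_iter <- d * (d - 1L)
  folds <- make_folds(n_tr, config$k, config$fold_seed)
  scfg <- score_config(kind = score, penalty = penalty, n_eff = n_tr)
  if (score == "cbic") {
    Z_full <- probit_pseudo(X, config$epsilon)
    theta <- select_bandwidth(Z_full, config)
    pobs <- pseudo_observations(X, folds, config$epsilon)
    provider <- cbic_provider(pobs, theta, scfg, config$density_floor)
  } else {
    Xs <- scale(X)
    theta <- select_bandwidth(Xs, config)
    provider <- ngll_provider(X, folds, theta, scfg, config$density_floor)
  }
  res <- greedy_search(provider, d, max_iter = max_iter,
                       debug_checks = debug_checks, verbose = verbose)
  structure(list(graph = res$graph, tree = res$tree, trace = res$trace,
                 score = res$score, theta = theta, config = config,
                 score_kind = score, n_tr = n_tr, d = d,
                 cache_stats = provider$cache_stats()),
            class = "decomposable_fit")
}

#' Greedy search over decomposable graphs with a supplied score provider
#'
#' The optimization core of [learn_structure()], exposed separately so
#' alternative subset functionals (including stubs) can drive the same
#' machinery.
#'
#' @param provider A score provider exposing `kappa(A)`.
#' @param d Number of vertices.
#' @param max_iter Iteration cap.
#' @param debug_checks Verify chordality each iteration.
#' @param verbose Print accepted moves.
#' @return A list with `graph`, `tree`, `trace`, and the final `score`.
#' @export
greedy_search <- function(provider, d, max_iter = d * (d - 1L),
                          debug_checks = FALSE, verbose = FALSE) {
  g <- ug(d)
  tree <- clique_tree(g)
  score0 <- tryCatch(global_score(tree, provider), error = function(e) NaN)
  if (!is.finite(score0)) {
    warning("no finite score on the empty graph; returning it unchanged")
    return(list(graph = g, tree = tree, trace = empty_trace(), score = NaN))
  }
  score <- score0
  trace <- list()
  for (it in seq_len(max_iter)) {
    moves <- dplyr::bind_rows(valid_insertions(g, tree),
                              valid_deletions(g, tree))
    if (!nrow(moves)) break
    kind_v <- moves$kind; i_v <- moves$i; j_v <- moves$j; S_v <- moves$S
    deltas <- vapply(seq_len(nrow(moves)), function(r) {
      mv <- list(kind = kind_v[r], i = i_v[r], j = j_v[r], S = S_v[[r]])
      tryCatch(delta_move(mv, provider), error = function(e) NaN)
    }, numeric(1))
    ok <- is.finite(deltas) & deltas > 0
    if (!any(ok)) break
    idx <- which(ok)
    cd <- deltas[idx]
    pick <- idx[order(-cd, kind_v[idx] != "insert", i_v[idx],
                      j_v[idx])[1L]]
    mv <- list(kind = kind_v[pick], i = i_v[pick], j = j_v[pick],
               S = S_v[[pick]])
    tree <- apply_move(tree, mv)
    g <- if (mv$kind == "insert") add_edge(g, mv$i, mv$j) else
      drop_edge(g, mv$i, mv$j)
    if (debug_checks && !is_chordal(g)) {
      stop("internal error: non-chordal state reached")
    }
    score <- score + deltas[pick]
    trace[[it]] <- tibble::tibble(
      iteration = it, kind = mv$kind, i = mv$i, j = mv$j,
      size_S = length(mv$S), delta = deltas[pick], score = score,
      n_cliques = length(tree$cliques),
      max_clique = max(lengths(tree$cliques)))
    if (verbose) {
      message(sprintf("iter %d: %s (%d,%d) delta=%.4f score=%.4f",
                      it, mv$kind, mv$i, mv$j, deltas[pick], score))
    }
  }
  trace <- if (length(trace)) dplyr::bind_rows(trace) else empty_trace()
  list(graph = g, tree = tree, trace = trace, score = score)
}

empty_trace <- function() {
  tibble::tibble(iteration = integer(0), kind = character(0),
                 i = integer(0), j = integer(0), size_S = integer(0),
                 delta = numeric(0), score = numeric(0),
                 n_cliques = integer(0), max_clique = integer(0))
}

#' @export
print.decomposable_fit <- function(x, ...) {
  cat(sprintf(
    "<decomposable_fit> %s: %d vertices, %d edges, %d cliques, score %.3f\n",
    toupper(x$score_kind), x$d, nrow(x$graph$edges),
    length(x$tree$cliques), x$score))
  invisible(x)
}

#' Tidy a fitted decomposable model into its edge list
#'
#' @param x A `decomposable_fit`.
#' @param ... Unused.
#' @return A tibble with columns `i`, `j`, one row per learned edge.
#' @method tidy decomposable_fit
#' @export
tidy.decomposable_fit <- function(x, ...) tidy(x$graph)

#' One-row summary of a fitted decomposable model
#'
#' @param x A `decomposable_fit`.
#' @param ... Unused.
#' @return A tibble with the score kind, edge/clique counts, the largest
#'   clique, iteration count and final score.
#' @method glance decomposable_fit
#' @importFrom generics glance
#' @export
glance.decomposable_fit <- function(x, ...) {
  tibble::tibble(
    score_kind = x$score_kind,
    n_edges = nrow(x$graph$edges),
    n_cliques = length(x$tree$cliques),
    max_clique = max(lengths(x$tree$cliques)),
    iterations = nrow(x$trace),
    score = x$score,
    n_tr = x$n_tr,
    d = x$d)
}

#' Plot a fitted decomposable model
#'
#' Draws the learned graph with a force-directed layout.
#'
#' @param object A `decomposable_fit` (or a `ug`).
#' @param labels Optional vertex labels (defaults to indices).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decomposable_fit
#' @importFrom ggplot2 autoplot
#' @export
autoplot.decomposable_fit <- function(object, labels = NULL, ...) {
  autoplot(object$graph, labels = labels, ...)
}

#' @rdname autoplot.decomposable_fit
#' @method autoplot ug
#' @export
autoplot.ug <- function(object, labels = NULL, ...) {
  if (is.null(labels)) labels <- as.character(seq_len(object$d))
  ig <- igraph::make_empty_graph(object$d, directed = FALSE)
  if (nrow(object$edges)) {
    ig <- igraph::add_edges(ig, t(object$edges))
  }
  xy <- withr::with_seed(1L, igraph::layout_with_fr(ig))
  nodes <- tibble::tibble(x = xy[, 1], y = xy[, 2], label = labels)
  if (nrow(object$edges)) {
    segs <- tibble::tibble(
      x = xy[object$edges[, 1L], 1], y = xy[object$edges[, 1L], 2],
      xend = xy[object$edges[, 2L], 1], yend = xy[object$edges[, 2L], 2])
  } else {
    segs <- tibble::tibble(x = numeric(0), y = numeric(0),
                           xend = numeric(0), yend = numeric(0))
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = -1, size = 3) +
    ggplot2::theme_void()
}
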