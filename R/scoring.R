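#' Score configuration
#'
#' The copula-information BIC-type score (`"cbic"`) combines the estimated
#' copula information of cliques and separators with an additive complexity
#' penalty: for a subset `A`,
#' `kappa(A) = n_eff * psi(A) - (log(n_eff) / 2) * lambda(A)`, with
#' `lambda(A) = |A| (|A| + 1) / 2` by default (the `"linear"` alternative
#' uses `lambda(A) = |A|`). The cross-validated kernel log-likelihood
#' baseline (`"ng_ll"`) uses the same clique-minus-separator aggregation
#' with the out-of-fold mean log density of a raw-scale KDE and no penalty.
#'
#' @param kind `"cbic"` or `"ng_ll"`.
#' @param penalty `"quadratic"` (`|A|(|A|+1)/2`) or `"linear"` (`|A|`).
#' @param n_eff Effective sample size used in the `n` and `log(n)` factors:
#'   the number of training observations the subset functionals are
#'   estimated from.
#' @return A list of class `score_config`.
#' @export
score_config <- function(kind = c("cbic", "ng_ll"),
                         penalty = c("quadratic", "linear"),
                         n_eff) {
  kind <- match.arg(kind)
  penalty <- match.arg(penalty)
  stopifnot(n_eff >= 2)
  structure(list(kind = kind, penalty = penalty, n_eff = n_eff),
            class = "score_config")
}

lambda_size <- function(A, penalty = "quadratic") {
  a <- length(A)
  if (penalty == "quadratic") a * (a + 1) / 2 else a
}

subset_key <- function(A) paste0("s", paste(sort(A), collapse = ","))

#' Score providers
#'
#' A score provider exposes `kappa(A)` — the penalized local score of a
#' variable subset — backed by a cache keyed on the canonical sorted subset,
#' so the four-term move deltas share evaluations across the whole search.
#' `cbic_provider()` uses the out-of-fold copula information [psi_kde()];
#' `ngll_provider()` uses the out-of-fold raw-scale KDE log-likelihood (no
#' pseudo-observations, no probit transform, no penalty term), with its
#' bandwidth selected by the same leave-one-out procedure on the
#' standardized data.
#'
#' @param pobs A [pseudo_observations()] object.
#' @param theta A [select_bandwidth()] result (or numeric vector).
#' @param config A [score_config()].
#' @param density_floor Density floor passed to the estimators.
#' @return A list with functions `kappa(A)`, `psi(A)`, and `cache_stats()`.
#' @export
cbic_provider <- function(pobs, theta, config,
                          density_floor = 1e-100) {
  if (inherits(theta, "bandwidth")) theta <- theta$theta
  cache <- new.env(parent = emptyenv())
  hits <- 0L; misses <- 0L
  psi_fun <- function(A) psi_kde(A, pobs, theta, density_floor)
  kappa <- function(A) {
    key <- subset_key(A)
    if (!is.null(val <- cache[[key]])) {
      hits <<- hits + 1L
      return(val)
    }
    misses <<- misses + 1L
    val <- config$n_eff * psi_fun(A) -
      (log(config$n_eff) / 2) * lambda_size(A, config$penalty)
    cache[[key]] <- val
    val
  }
  list(kappa = kappa, psi = psi_fun,
       cache_stats = function() c(hits = hits, misses = misses),
       kind = "cbic")
}

#' @rdname cbic_provider
#' @param X Raw numeric training matrix (standardized internally).
#' @param folds Fold labels from [make_folds()].
#' @export
ngll_provider <- function(X, folds, theta, config,
                          density_floor = 1e-100) {
  if (inherits(theta, "bandwidth")) theta <- theta$theta
  X <- scale(as.matrix(X))
  n_tr <- nrow(X)
  k <- max(folds)
  train_rows <- lapply(seq_len(k), function(r) which(folds != r))
  test_rows <- lapply(seq_len(k), function(r) which(folds == r))
  cache <- new.env(parent = emptyenv())
  hits <- 0L; misses <- 0L
  phi_fun <- function(A) {
    A <- sort(as.integer(A))
    if (length(A) == 0L) return(0)
    total <- 0
    for (r in seq_len(k)) {
      q <- X[test_rows[[r]], A, drop = FALSE]
      ctr <- X[train_rows[[r]], A, drop = FALSE]
      lk <- cross_log_kde(q, ctr, theta[A])
      total <- total + sum(pmax(lk, log(density_floor)))
    }
    total / n_tr
  }
  kappa <- function(A) {
    key <- subset_key(A)
    if (!is.null(val <- cache[[key]])) {
      hits <<- hits + 1L
      return(val)
    }
    misses <<- misses + 1L
    val <- config$n_eff * phi_fun(A)
    cache[[key]] <- val
    val
  }
  list(kappa = kappa, psi = phi_fun,
       cache_stats = function() c(hits = hits, misses = misses),
       kind = "ng_ll")
}

#' Local score change of a single-edge move
#'
#' For an insertion with separator `S`, the score difference is the
#' four-term combination
#' `kappa(S + {i,j}) - kappa(S + i) - kappa(S + j) + kappa(S)`;
#' a deletion is its negation. A non-finite value marks the move as
#' inadmissible (it is deterministically never selected).
#'
#' @param move A one-row move tibble (or list) from [valid_insertions()] /
#'   [valid_deletions()].
#' @param provider A score provider ([cbic_provider()] or
#'   [ngll_provider()]).
#' @return The scalar score change (possibly non-finite).
#' @export
delta_move <- function(move, provider) {
  if (is.data.frame(move)) {
    stopifnot(nrow(move) == 1L)
    move <- list(kind = move$kind, i = move$i, j = move$j, S = move$S[[1L]])
  }
  S <- move$S
  kap <- provider$kappa
  ins <- kap(c(S, move$i, move$j)) - kap(c(S, move$i)) -
    kap(c(S, move$j)) + kap(S)
  if (identical(move$kind, "insert")) ins else -ins
}

#' Global score of a decomposable model
#'
#' The clique-minus-separator aggregation of the penalized local scores over
#' the maintained clique tree: `sum kappa(K) - sum kappa(S)`, separators
#' counted with their tree-edge multiplicity.
#'
#' @param tree A `clique_tree`.
#' @param provider A score provider.
#' @return The scalar global score.
#' @export
global_score <- function(tree, provider) {
  s <- sum(vapply(tree$cliques, provider$kappa, numeric(1)))
  if (length(tree$separators)) {
    s <- s - sum(vapply(tree$separators, provider$kappa, numeric(1)))
  }
  s
}
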