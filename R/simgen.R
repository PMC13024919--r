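#' Sample a chordal ground-truth graph
#'
#' Draws an Erdos-Renyi graph `G(d, rho)` and chordalizes it by the
#' elimination game with a minimum-degree heuristic (lexicographic
#' tie-breaks), so the output is a deterministic function of the seed, is
#' chordal, and contains every originally drawn edge.
#'
#' @param d Number of vertices.
#' @param rho Edge probability in (0, 1).
#' @param seed Integer seed.
#' @return A chordal [ug()].
#' @export
sample_chordal_truth <- function(d, rho, seed = 1L) {
  stopifnot(rho > 0, rho < 1, d >= 2)
  g0 <- withr::with_seed(seed, {
    pairs <- t(utils::combn(d, 2L))
    draw <- stats::runif(nrow(pairs)) < rho
    ug(d, pairs[draw, , drop = FALSE])
  })
  triangulate_min_degree(g0)
}

# elimination game: repeatedly eliminate a minimum-degree vertex (smallest
# index on ties), connecting its remaining neighbours; fill edges are added
# to the output graph
triangulate_min_degree <- function(g) {
  d <- g$d
  adj <- lapply(adjacency_list(g), function(x) sort(unique(x)))
  alive <- rep(TRUE, d)
  fill <- list()
  for (step in seq_len(d)) {
    deg <- vapply(seq_len(d), function(v) {
      if (alive[v]) sum(alive[adj[[v]]]) else NA_integer_
    }, integer(1))
    v <- which.min(deg) # NA ignored; first minimum = smallest index
    nb <- adj[[v]][alive[adj[[v]]]]
    if (length(nb) >= 2L) {
      for (a_i in seq_len(length(nb) - 1L)) {
        for (b_i in (a_i + 1L):length(nb)) {
          a <- nb[a_i]; b <- nb[b_i]
          if (!(b %in% adj[[a]])) {
            adj[[a]] <- sort(c(adj[[a]], b))
            adj[[b]] <- sort(c(adj[[b]], a))
            fill[[length(fill) + 1L]] <- c(a, b)
          }
        }
      }
    }
    alive[v] <- FALSE
  }
  extra <- if (length(fill)) do.call(rbind, fill) else NULL
  ug(g$d, rbind(g$edges, extra))
}

#' Build a copula-Gaussian precision and correlation from a graph
#'
#' Assigns Gamma(shape = 2, rate = 1) weights to the graph's edges, forms
#' the ridge-regularized graph Laplacian precision `Q = nu * I + D - W`
#' (strictly diagonally dominant, hence positive definite, with off-diagonal
#' support exactly on the edge set), and standardizes the implied covariance
#' `Q^{-1}` to a correlation matrix `R`. The standardized precision `SQS`
#' keeps the zero pattern of `Q`, so latent conditional independences match
#' the non-edges of `g` exactly.
#'
#' @param g A [ug()].
#' @param nu Ridge constant, positive. The main free knob for signal
#'   strength; `nu = 1` by default.
#' @param seed Integer seed for the edge weights; `NULL` continues the
#'   current RNG stream (used internally so one seed drives a whole
#'   dataset).
#' @return A list with `Q`, `R` (correlation), `SQS` (standardized
#'   precision), and the weight matrix `W`.
#' @export
build_correlation <- function(g, nu = 1, seed = NULL) {
  stopifnot(nu > 0)
  draw <- function() {
    d <- g$d
    W <- matrix(0, d, d)
    ne <- nrow(g$edges)
    if (ne) {
      wts <- stats::rgamma(ne, shape = 2, rate = 1)
      W[g$edges] <- wts
      W[g$edges[, c(2L, 1L), drop = FALSE]] <- wts
    }
    W
  }
  W <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  D <- diag(rowSums(W), g$d)
  Q <- nu * diag(g$d) + D - W
  Sigma <- solve(Q)
  s <- sqrt(diag(Sigma))
  R <- Sigma / tcrossprod(s)
  SQS <- Q * tcrossprod(s)
  list(Q = Q, R = R, SQS = SQS, W = W)
}

#' Generate the synthetic benchmark dataset
#'
#' One seed drives the full pipeline in a fixed order — ground-truth graph,
#' Gamma edge weights, latent Gaussian draws — so a seed reproduces the
#' dataset bit for bit. Latent vectors are sampled from
#' `N(0, (SQS)^{-1})`, mapped to the unit cube by the normal CDF, and the
#' three marginal families are produced by component-wise quantile
#' transforms of the *same* uniform matrix: standard normal (for which `X`
#' equals the latent `Z` exactly), unit-rate exponential, and
#' Beta(1/2, 1/2). All three therefore share identical column ranks; only
#' the marginal shapes differ.
#'
#' @param d Number of variables.
#' @param n Number of observations.
#' @param rho Erdos-Renyi edge probability for the ground truth.
#' @param nu Ridge constant of the latent precision.
#' @param seed Integer seed.
#' @param marginals Character subset of
#'   `c("normal", "exponential", "beta")`.
#' @return A list with `truth` (chordal [ug()]), `X` (named list of n-by-d
#'   matrices, one per marginal family), `U` (shared uniforms), and the
#'   `Q`, `R`, `SQS` matrices.
#' @export
simulate_benchmark <- function(d = 30, n = 2000, rho = 0.1, nu = 1,
                               seed = 1L,
                               marginals = c("normal", "exponential",
                                             "beta")) {
  marginals <- match.arg(marginals, several.ok = TRUE)
  truth <- sample_chordal_truth(d, rho, seed)
  out <- withr::with_seed(seed + 1L, {
    corr <- build_correlation(truth, nu, seed = NULL)
    L <- chol(corr$R)
    Z <- matrix(stats::rnorm(n * d), n, d) %*% L
    list(corr = corr, Z = Z)
  })
  U <- stats::pnorm(out$Z)
  X <- list()
  for (fam in marginals) {
    X[[fam]] <- switch(fam,
      normal = out$Z,
      exponential = stats::qexp(U, rate = 1),
      beta = stats::qbeta(U, 0.5, 0.5))
  }
  list(truth = truth, X = X, U = U, Q = out$corr$Q, R = out$corr$R,
       SQS = out$corr$SQS)
}
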