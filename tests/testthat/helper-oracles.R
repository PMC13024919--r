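# Independent oracles used across the suite. Graph-theoretic properties are
# cross-checked against igraph (a fully independent implementation);
# clique-tree updates are checked against rebuild-from-scratch.

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(g$d, directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

oracle_is_chordal <- function(g) igraph::is_chordal(as_igraph(g))$chordal

oracle_max_cliques <- function(g) {
  cl <- lapply(igraph::max_cliques(as_igraph(g)), function(x) sort(as.integer(x)))
  cl[order(vapply(cl, function(k) paste(sprintf("%06d", k), collapse = ","),
                  character(1)))]
}

separator_multiset <- function(tree) {
  sort(vapply(tree$separators, paste, character(1), collapse = ","))
}

# random chordal graph obtained by a random walk of brute-force-validated
# single-edge moves from the empty graph (independent of the package's own
# admissibility code)
random_chordal_walk <- function(d, steps, p_delete = 0.3) {
  g <- ug(d)
  for (s in seq_len(steps)) {
    pairs <- t(utils::combn(d, 2L))
    keys <- paste(pairs[, 1], pairs[, 2])
    ekeys <- paste(g$edges[, 1], g$edges[, 2])
    want_delete <- stats::runif(1) < p_delete && nrow(g$edges) > 0
    cand <- if (want_delete) pairs[keys %in% ekeys, , drop = FALSE] else
      pairs[!(keys %in% ekeys), , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[sample(nrow(cand)), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      g2 <- if (want_delete) drop_edge_(g, cand[r, 1], cand[r, 2]) else
        add_edge_(g, cand[r, 1], cand[r, 2])
      if (oracle_is_chordal(g2)) {
        g <- g2
        break
      }
    }
  }
  g
}

edgekeys <- function(g) paste(g$edges[, 1], g$edges[, 2], sep = "-")

# multiset difference on character keys
setdiff_multi <- function(a, b) {
  for (x in b) {
    hit <- match(x, a)
    if (!is.na(hit)) a <- a[-hit]
  }
  a
}

add_edge_ <- function(g, i, j) ug(g$d, rbind(g$edges, c(i, j)))
drop_edge_ <- function(g, i, j) {
  keep <- !(g$edges[, 1] == min(i, j) & g$edges[, 2] == max(i, j))
  ug(g$d, g$edges[keep, , drop = FALSE])
}

# bivariate Gaussian-copula sample with given latent correlation and
# optional marginal quantile transforms
rgauss_copula2 <- function(n, r, transform = identity) {
  Z <- matrix(stats::rnorm(n * 2), n, 2) %*%
    chol(matrix(c(1, r, r, 1), 2))
  apply(Z, 2, transform)
}
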