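#' Clique trees (junction trees) for chordal graphs
#'
#' A clique tree represents a chordal graph by its maximal cliques, connected
#' into a tree whose edges carry separators (the intersection of the two
#' incident cliques). Separators enter the score with their tree-edge
#' multiplicity, so the maintained tree is the score's reference
#' representation during search. Disconnected graphs are handled by joining
#' components through empty separators, which are score-neutral.
#'
#' The tree is a maximum-weight spanning tree of the clique graph under
#' `w(K, K') = |K intersect K'|` (Kruskal, ties broken by lexicographic clique
#' order so the construction is reproducible).
#'
#' @param g A chordal `ug` object.
#' @return An object of class `clique_tree` with fields `cliques` (list of
#'   sorted integer vectors in canonical order), `edges` (an `(m-1) x 2`
#'   matrix of clique indices), `separators` (list parallel to `edges`), and
#'   `d`.
#' @export
clique_tree <- function(g) {
  stopifnot(inherits(g, "ug"))
  cliques <- maximal_cliques(g)
  tree_from_cliques(cliques, g$d)
}

# Kruskal maximum-weight spanning tree over an already-canonical clique list.
tree_from_cliques <- function(cliques, d) {
  m <- length(cliques)
  if (m <= 1L) {
    return(structure(
      list(cliques = cliques,
           edges = matrix(integer(0), ncol = 2L),
           separators = list(), d = d),
      class = "clique_tree"))
  }
  pairs <- utils::combn(m, 2L)
  w <- integer(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    w[p] <- length(intersect(cliques[[pairs[1L, p]]], cliques[[pairs[2L, p]]]))
  }
  ord <- order(-w, pairs[1L, ], pairs[2L, ])
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ek <- integer(m - 1L); el <- integer(m - 1L)
  seps <- vector("list", m - 1L)
  taken <- 0L
  for (p in ord) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <- rb
      taken <- taken + 1L
      ek[taken] <- a; el[taken] <- b
      seps[[taken]] <- sort(intersect(cliques[[a]], cliques[[b]]))
      if (taken == m - 1L) break
    }
  }
  structure(
    list(cliques = cliques, edges = cbind(ek, el), separators = seps, d = d),
    class = "clique_tree")
}

#' @export
print.clique_tree <- function(x, ...) {
  cat(sprintf("<clique_tree> %d cliques over %d vertices\n",
              length(x$cliques), x$d))
  invisible(x)
}

#' Separator multiset of a clique tree
#'
#' @param tree A `clique_tree`.
#' @return A list of sorted integer vectors, one per tree edge (possibly
#'   empty vectors for component-joining edges).
#' @export
separators <- function(tree) tree$separators

#' Serialize a clique tree to JSON
#'
#' @param tree A `clique_tree`.
#' @param path Optional file path; when omitted the JSON string is returned.
#' @return JSON text (invisibly, when written to a file).
#' @export
clique_tree_json <- function(tree, path = NULL) {
  obj <- list(
    cliques = lapply(tree$cliques, as.integer),
    tree_edges = lapply(seq_len(nrow(tree$edges)), function(r) {
      list(tree$edges[r, 1L], tree$edges[r, 2L],
           as.integer(tree$separators[[r]]))
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

tree_adjacency <- function(tree) {
  m <- length(tree$cliques)
  adj <- vector("list", m)
  for (q in seq_len(m)) adj[[q]] <- integer(0)
  if (nrow(tree$edges)) {
    for (r in seq_len(nrow(tree$edges))) {
      a <- tree$edges[r, 1L]; b <- tree$edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# BFS distances in the clique tree from a source clique
tree_distances <- function(adj, from) {
  m <- length(adj)
  dist <- rep(NA_integer_, m)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[v]]) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[v] + 1L
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

# vertex path between two cliques (sequence of clique indices)
tree_path <- function(adj, from, to) {
  m <- length(adj)
  prev <- rep(NA_integer_, m)
  seen <- logical(m)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v == to) break
    for (nb in adj[[v]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        prev[nb] <- v
        queue <- c(queue, nb)
      }
    }
  }
  path <- to
  while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
  path
}

empty_move_tbl <- function() {
  tibble::tibble(kind = character(0), i = integer(0), j = integer(0),
                 S = list(), k = integer(0), l = integer(0))
}

#' Admissible single-edge deletions
#'
#' An edge can be deleted while preserving decomposability exactly when it is
#' contained in a single maximal clique `K`; the move then splits `K` into
#' `S + i` and `S + j` around the separator `S = K \ {i, j}`.
#'
#' @param g A chordal `ug`.
#' @param tree Its `clique_tree`.
#' @return A tibble of moves with columns `kind` (`"delete"`), `i`, `j`,
#'   `S` (list-column of sorted integer vectors), and `k` (index of the
#'   containing clique; `l` is `NA`).
#' @export
valid_deletions <- function(g, tree) {
  if (!nrow(g$edges)) return(empty_move_tbl())
  rows <- list()
  for (r in seq_len(nrow(g$edges))) {
    i <- unname(g$edges[r, 1L]); j <- unname(g$edges[r, 2L])
    inq <- which(vapply(tree$cliques, function(K) (i %in% K) && (j %in% K),
                        logical(1)))
    if (length(inq) == 1L) {
      K <- tree$cliques[[inq]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = "delete", i = i, j = j,
        S = list(sort(setdiff(K, c(i, j)))), k = inq, l = NA_integer_)
    }
  }
  if (!length(rows)) return(empty_move_tbl())
  dplyr::bind_rows(rows)
}

#' Admissible single-edge insertions
#'
#' A non-edge `{i, j}` can be inserted while preserving decomposability
#' exactly when, taking the closest pair of cliques `K_k` containing `i` and
#' `K_l` containing `j` in the maintained tree, the minimum separator weight
#' along the tree path between them equals `|K_k intersect K_l|`. The move's
#' separator is `S = K_k intersect K_l`, and the insertion creates the new
#' maximal clique `S + {i, j}`. Ties among equally close clique pairs are
#' broken by smallest clique index (any valid representative yields the same
#' `S`).
#'
#' @inheritParams valid_deletions
#' @return A tibble of moves with columns `kind` (`"insert"`), `i`, `j`, `S`
#'   (list-column), and the clique indices `k`, `l`.
#' @export
valid_insertions <- function(g, tree) {
  d <- g$d
  if (d < 2L) return(empty_move_tbl())
  adj <- tree_adjacency(tree)
  m <- length(tree$cliques)
  member <- lapply(seq_len(d), function(v) {
    which(vapply(tree$cliques, function(K) v %in% K, logical(1)))
  })
  distm <- matrix(0L, m, m)
  for (q in seq_len(m)) distm[q, ] <- tree_distances(adj, q)
  present <- matrix(FALSE, d, d)
  if (nrow(g$edges)) {
    present[g$edges] <- TRUE
  }
  ii <- integer(0); jj <- integer(0); kk <- integer(0); ll <- integer(0)
  Ss <- list()
  for (i in seq_len(d - 1L)) {
    for (j in (i + 1L):d) {
      if (present[i, j]) next
      best <- find_closest_cliques(distm, member[[i]], member[[j]])
      k <- best$k; l <- best$l
      S <- sort(intersect(tree$cliques[[k]], tree$cliques[[l]]))
      ok <- if (best$dist == 1L) {
        TRUE
      } else {
        path <- tree_path(adj, k, l)
        minw <- min(path_separator_sizes(tree, path))
        minw == length(S)
      }
      if (ok) {
        ii <- c(ii, i); jj <- c(jj, j); kk <- c(kk, k); ll <- c(ll, l)
        Ss[[length(Ss) + 1L]] <- S
      }
    }
  }
  if (!length(ii)) return(empty_move_tbl())
  tibble::tibble(kind = "insert", i = ii, j = jj, S = Ss, k = kk, l = ll)
}

# closest pair (k in Ks, l in Ls) by precomputed tree distance; ties by
# smallest clique indices (Ks, Ls are increasing)
find_closest_cliques <- function(distm, Ks, Ls) {
  sub <- distm[Ks, Ls, drop = FALSE]
  hit <- which(sub == min(sub), arr.ind = TRUE)
  pick <- hit[order(hit[, 1L], hit[, 2L])[1L], ]
  list(k = Ks[pick[1L]], l = Ls[pick[2L]], dist = min(sub))
}

path_separator_sizes <- function(tree, path) {
  sizes <- integer(length(path) - 1L)
  for (s in seq_len(length(path) - 1L)) {
    a <- path[s]; b <- path[s + 1L]
    r <- which((tree$edges[, 1L] == a & tree$edges[, 2L] == b) |
               (tree$edges[, 1L] == b & tree$edges[, 2L] == a))
    sizes[s] <- length(tree$separators[[r]])
  }
  sizes
}

#' Apply a validated move to a clique tree
#'
#' Updates the maximal-clique set incrementally: an insertion adds the new
#' clique `S + {i, j}` and absorbs any clique it subsumes (`S + i` or
#' `S + j`); a deletion splits the unique containing clique into `S + i` and
#' `S + j`, dropping either part when a neighbouring clique subsumes it. The
#' tree over the updated clique set is then re-derived as the maximum-weight
#' spanning tree (identical tie-break as [clique_tree()]), so the result is
#' exactly the tree that would be built for the edited graph.
#'
#' @param tree A `clique_tree`.
#' @param move A one-row move tibble from [valid_insertions()] or
#'   [valid_deletions()] (or a list with fields `kind`, `i`, `j`, `S`).
#' @return The updated `clique_tree`.
#' @export
apply_move <- function(tree, move) {
  if (is.data.frame(move)) {
    stopifnot(nrow(move) == 1L)
    move <- list(kind = move$kind, i = move$i, j = move$j, S = move$S[[1L]])
  }
  i <- unname(move$i); j <- unname(move$j); S <- unname(move$S)
  cliques <- tree$cliques
  if (identical(move$kind, "insert")) {
    K_star <- sort(c(S, i, j))
    subsumed <- vapply(cliques, function(K) all(K %in% K_star), logical(1))
    cliques <- c(cliques[!subsumed], list(K_star))
  } else if (identical(move$kind, "delete")) {
    K <- sort(c(S, i, j))
    is_K <- vapply(cliques, function(x) identical(x, K), logical(1))
    if (sum(is_K) != 1L) stop("delete move does not match a unique clique")
    cliques <- cliques[!is_K]
    for (part in list(sort(c(S, i)), sort(c(S, j)))) {
      contained <- any(vapply(cliques, function(K2) all(part %in% K2),
                              logical(1)))
      if (!contained) cliques <- c(cliques, list(part))
    }
  } else {
    stop("unknown move kind: ", move$kind)
  }
  cliques <- cliques[order(vapply(cliques, clique_label, character(1)))]
  tree_from_cliques(cliques, tree$d)
}

# graph represented by a clique tree (used by tests and the search loop)
graph_from_tree <- function(tree) {
  edges <- list()
  for (K in tree$cliques) {
    if (length(K) >= 2L) {
      edges[[length(edges) + 1L]] <- t(utils::combn(K, 2L))
    }
  }
  ug(tree$d, if (length(edges)) do.call(rbind, edges) else NULL)
}
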