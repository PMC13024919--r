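#' Undirected graphs on a fixed vertex set
#'
#' `ug()` constructs an undirected graph on vertices `1..d`. Edges are stored
#' canonically as a two-column integer matrix with `i < j`, ordered
#' lexicographically, with no duplicates and no self-loops. This is the
#' hypothesis space of the structure learner: decomposable (chordal) graphs
#' over the observed variables.
#'
#' @param d Number of vertices (positive integer).
#' @param edges Optional edges: a two-column matrix or data frame of vertex
#'   indices in `1..d`. Order within a pair and row order are irrelevant.
#' @return An object of class `ug` with fields `d` and `edges`.
#' @examples
#' g <- ug(4, rbind(c(1, 2), c(2, 3)))
#' is_chordal(g)
#' @export
ug <- function(d, edges = NULL) {
  d <- as.integer(d)
  stopifnot(length(d) == 1L, d >= 1L)
  em <- canonical_edges(edges, d)
  structure(list(d = d, edges = em), class = "ug")
}

canonical_edges <- function(edges, d) {
  if (is.null(edges) || NROW(edges) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  em <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(em) <- "integer"
  if (anyNA(em) || any(em < 1L) || any(em > d)) {
    stop("edge endpoints must be vertex indices in 1..d")
  }
  if (any(em[, 1L] == em[, 2L])) stop("self-loops are not allowed")
  em <- cbind(i = pmin(em[, 1L], em[, 2L]), j = pmax(em[, 1L], em[, 2L]))
  em <- unique(em)
  em[order(em[, 1L], em[, 2L]), , drop = FALSE]
}

#' @export
print.ug <- function(x, ...) {
  cat(sprintf("<ug> %d vertices, %d edges\n", x$d, nrow(x$edges)))
  invisible(x)
}

#' @export
format.ug <- function(x, ...) {
  sprintf("<ug: d=%d, %d edges>", x$d, nrow(x$edges))
}

edge_key <- function(em) paste(em[, 1L], em[, 2L], sep = "-")

has_edge <- function(g, i, j) {
  a <- min(i, j); b <- max(i, j)
  any(g$edges[, 1L] == a & g$edges[, 2L] == b)
}

add_edge <- function(g, i, j) {
  ug(g$d, rbind(g$edges, c(min(i, j), max(i, j))))
}

drop_edge <- function(g, i, j) {
  a <- min(i, j); b <- max(i, j)
  keep <- !(g$edges[, 1L] == a & g$edges[, 2L] == b)
  ug(g$d, g$edges[keep, , drop = FALSE])
}

adjacency_list <- function(g) {
  adj <- vector("list", g$d)
  for (v in seq_len(g$d)) adj[[v]] <- integer(0)
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      i <- g$edges[r, 1L]; j <- g$edges[r, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' Tidy an undirected graph into an edge tibble
#'
#' @param x A `ug` object.
#' @param ... Unused.
#' @return A tibble with integer columns `i`, `j` (`i < j`), one row per edge.
#' @method tidy ug
#' @importFrom generics tidy
#' @export
tidy.ug <- function(x, ...) {
  tibble::tibble(i = as.integer(x$edges[, 1L]), j = as.integer(x$edges[, 2L]))
}

# Maximum cardinality search. Returns the visit order, the earlier-neighbour
# sets M(v), and whether the graph is chordal (Tarjan-Yannakakis test: for
# each v, M(v) minus its latest-visited member must be adjacent to it).
mcs <- function(g) {
  d <- g$d
  adj <- adjacency_list(g)
  wt <- integer(d)
  visited <- logical(d)
  ord <- integer(d)
  pos <- integer(d)
  M <- vector("list", d)
  chordal <- TRUE
  for (step in seq_len(d)) {
    cand <- which(!visited)
    v <- cand[which.max(wt[cand])] # which.max takes the first => smallest index tie-break
    visited[v] <- TRUE
    ord[step] <- v
    pos[v] <- step
    mv <- adj[[v]][visited[adj[[v]]] & adj[[v]] != v]
    mv <- setdiff(mv, v)
    M[[v]] <- mv
    if (length(mv) >= 2L) {
      parent <- mv[which.max(pos[mv])]
      rest <- setdiff(mv, parent)
      if (!all(rest %in% adj[[parent]])) chordal <- FALSE
    }
    nb <- adj[[v]]
    wt[nb[!visited[nb]]] <- wt[nb[!visited[nb]]] + 1L
  }
  list(order = ord, M = M, chordal = chordal)
}

#' Test whether a graph is chordal
#'
#' A graph is chordal (equivalently, decomposable) when every cycle of length
#' at least four has a chord. The test runs maximum cardinality search and
#' checks that it yields a perfect elimination ordering.
#'
#' @param g A `ug` object.
#' @return `TRUE` or `FALSE`.
#' @export
is_chordal <- function(g) {
  stopifnot(inherits(g, "ug"))
  mcs(g)$chordal
}

#' Maximal cliques of a chordal graph
#'
#' Enumerates the maximal cliques from a maximum cardinality search ordering;
#' a chordal graph on `d` vertices has at most `d` maximal cliques. Cliques
#' are returned as sorted integer vectors in a canonical (lexicographic)
#' order.
#'
#' @param g A chordal `ug` object.
#' @return A list of sorted integer vectors.
#' @export
maximal_cliques <- function(g) {
  stopifnot(inherits(g, "ug"))
  m <- mcs(g)
  if (!m$chordal) stop("graph is not chordal")
  cand <- lapply(m$order, function(v) sort(c(v, m$M[[v]])))
  keep_maximal_sets(cand)
}

# drop sets that are proper subsets of another set in the list; canonical order
keep_maximal_sets <- function(sets) {
  sets <- unique(sets)
  n <- length(sets)
  keep <- rep(TRUE, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b && keep[a] &&
          length(sets[[a]]) < length(sets[[b]]) &&
          all(sets[[a]] %in% sets[[b]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  sets <- sets[keep]
  sets[order(vapply(sets, clique_label, character(1)))]
}

clique_label <- function(k) paste(sprintf("%06d", k), collapse = ",")

#' Read / write an edge-list TSV
#'
#' Plain-text interchange format for graphs: a header line `i<TAB>j` followed
#' by one edge per line with 1-based vertex indices, `i < j`.
#'
#' @param path File path.
#' @param g A `ug` object (for writing).
#' @param d Vertex count (for reading; inferred from the data when omitted).
#' @return `read_graph_tsv()` returns a `ug`; `write_graph_tsv()` returns the
#'   path invisibly.
#' @export
read_graph_tsv <- function(path, d = NULL) {
  tab <- utils::read.delim(path, sep = "\t")
  if (is.null(d)) d <- if (nrow(tab)) max(tab[[1]], tab[[2]]) else 1L
  ug(d, as.matrix(tab[, 1:2]))
}

#' @rdname read_graph_tsv
#' @export
write_graph_tsv <- function(g, path) {
  df <- data.frame(i = g$edges[, 1L], j = g$edges[, 2L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
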