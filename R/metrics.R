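#' Edge-recovery metrics for an estimated graph
#'
#' Compares a learned undirected graph with the ground truth by exact edge
#' set arithmetic: true positives, false positives, false negatives, the
#' structural Hamming distance (SHD, the number of single-edge edits turning
#' one graph into the other — for undirected graphs `FP + FN`), precision,
#' recall, and F1. A degenerate precision (empty learned graph) or recall
#' (empty truth) is reported as 0 together with an explicit flag so that
#' benchmark aggregation stays total.
#'
#' @param truth The ground-truth [ug()].
#' @param learned The estimated [ug()]; must share the vertex count.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `shd`,
#'   `precision`, `recall`, `f1`, `precision_defined`, `recall_defined`.
#' @examples
#' g1 <- ug(4, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' g2 <- ug(4, rbind(c(1, 2), c(2, 4)))
#' graph_recovery(g1, g2)
#' @export
graph_recovery <- function(truth, learned) {
  stopifnot(inherits(truth, "ug"), inherits(learned, "ug"))
  if (truth$d != learned$d) stop("vertex counts differ")
  te <- edge_key(truth$edges)
  le <- edge_key(learned$edges)
  tp <- length(intersect(le, te))
  fp <- length(setdiff(le, te))
  fn <- length(setdiff(te, le))
  prec_def <- (tp + fp) > 0L
  rec_def <- (tp + fn) > 0L
  precision <- if (prec_def) tp / (tp + fp) else 0
  recall <- if (rec_def) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn, shd = fp + fn,
                 precision = precision, recall = recall, f1 = f1,
                 precision_defined = prec_def, recall_defined = rec_def)
}

#' Structural Hamming distance from adjacency matrices
#'
#' The half-sum of absolute adjacency differences; provided as the
#' adjacency-matrix route to the same quantity that [graph_recovery()]
#' computes by edge-set arithmetic.
#'
#' @inheritParams graph_recovery
#' @return A nonnegative integer.
#' @export
shd_adjacency <- function(truth, learned) {
  stopifnot(truth$d == learned$d)
  A <- adjacency_matrix(truth)
  B <- adjacency_matrix(learned)
  as.integer(sum(abs(A - B)) / 2)
}

adjacency_matrix <- function(g) {
  A <- matrix(0L, g$d, g$d)
  if (nrow(g$edges)) {
    A[g$edges] <- 1L
    A[g$edges[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  A
}
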