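test_that("chordality test matches the definition on canonical graphs", {
  c4 <- ug(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  expect_false(is_chordal(c4))
  expect_true(is_chordal(ug(3, rbind(c(1, 2), c(2, 3), c(1, 3)))))
  expect_true(is_chordal(ug(5)))
  expect_true(is_chordal(add_edge_(c4, 2, 4))) # chord restores chordality
})

test_that("maximal cliques are exactly the subset-maximal complete sets", {
  path <- ug(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(maximal_cliques(path), list(c(1L, 2L), c(2L, 3L)))
  tri <- ug(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(maximal_cliques(tri), list(c(1L, 2L, 3L)))
  kite <- ug(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4), c(2, 4)))
  expect_equal(maximal_cliques(kite), list(c(1L, 2L, 4L), c(2L, 3L, 4L)))
  expect_error(maximal_cliques(ug(4, rbind(c(1, 2), c(2, 3), c(3, 4),
                                           c(1, 4)))),
               "chordal")
})

test_that("clique tree satisfies its structural invariants", {
  path <- ug(3, rbind(c(1, 2), c(2, 3)))
  tr <- clique_tree(path)
  expect_equal(tr$cliques, list(c(1L, 2L), c(2L, 3L)))
  expect_equal(nrow(tr$edges), 1L)
  expect_equal(tr$separators[[1]], 2L)

  single <- clique_tree(ug(3, rbind(c(1, 2), c(2, 3), c(1, 3))))
  expect_equal(length(single$cliques), 1L)
  expect_equal(length(single$separators), 0L)

  # disconnected components joined through an empty separator
  two <- clique_tree(ug(4, rbind(c(1, 2), c(3, 4))))
  expect_equal(length(two$cliques), 2L)
  expect_equal(two$separators[[1]], integer(0))
})

test_that("deletion admissibility follows the unique-containing-clique rule", {
  tri <- ug(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  vd <- valid_deletions(tri, clique_tree(tri))
  expect_equal(nrow(vd), 3L)
  # each deletion's separator is the remaining vertex
  expect_equal(vd$S[[which(vd$i == 1 & vd$j == 2)]], 3L)

  kite <- ug(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4), c(2, 4)))
  vdk <- valid_deletions(kite, clique_tree(kite))
  expect_false(any(vdk$i == 2 & vdk$j == 4)) # chord lies in two cliques
  expect_equal(nrow(vdk), 4L)

  e1 <- ug(2, rbind(c(1, 2)))
  vde <- valid_deletions(e1, clique_tree(e1))
  expect_equal(vde$S[[1]], integer(0))
})

test_that("insertion admissibility follows the junction-tree path criterion", {
  p3 <- ug(3, rbind(c(1, 2), c(2, 3)))
  vi <- valid_insertions(p3, clique_tree(p3))
  expect_equal(nrow(vi), 1L)
  expect_equal(vi$S[[1]], 2L)

  p4 <- ug(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  vi4 <- valid_insertions(p4, clique_tree(p4))
  expect_true(any(vi4$i == 1 & vi4$j == 3))
  expect_false(any(vi4$i == 1 & vi4$j == 4)) # would create a chordless C4

  empty <- ug(5)
  vie <- valid_insertions(empty, clique_tree(empty))
  expect_equal(nrow(vie), choose(5, 2))
  expect_true(all(lengths(vie$S) == 0L))
})

test_that("apply_move reproduces the rebuilt clique tree on worked examples", {
  p3 <- ug(3, rbind(c(1, 2), c(2, 3)))
  tr <- clique_tree(p3)
  vi <- valid_insertions(p3, tr)
  merged <- apply_move(tr, vi[1, ])
  expect_equal(merged$cliques, list(c(1L, 2L, 3L)))
  expect_equal(length(merged$separators), 0L)

  tri <- ug(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  trt <- clique_tree(tri)
  vd <- valid_deletions(tri, trt)
  split <- apply_move(trt, vd[vd$i == 1 & vd$j == 3, ])
  expect_equal(split$cliques, list(c(1L, 2L), c(2L, 3L)))
  expect_equal(split$separators[[1]], 2L)

  # delete an edge inside one of two overlapping cliques
  g <- ug(4, rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4)))
  trg <- clique_tree(g)
  vdg <- valid_deletions(g, trg)
  mv <- vdg[vdg$i == 1 & vdg$j == 2, ]
  out <- apply_move(trg, mv)
  expect_equal(out$cliques, clique_tree(drop_edge_(g, 1, 2))$cliques)
})

test_that("moves match the brute-force edit-then-test oracle on random chordal graphs", {
  set.seed(101)
  for (rep in 1:25) {
    d <- sample(4:7, 1)
    g <- random_chordal_walk(d, steps = sample(3:10, 1))
    tr <- clique_tree(g)
    expect_true(oracle_is_chordal(g))
    expect_equal(tr$cliques, oracle_max_cliques(g))
    vi <- valid_insertions(g, tr)
    vd <- valid_deletions(g, tr)
    for (i in 1:(d - 1)) {
      for (j in (i + 1):d) {
        present <- any(g$edges[, 1] == i & g$edges[, 2] == j)
        if (present) {
          ok <- oracle_is_chordal(drop_edge_(g, i, j))
          expect_equal(any(vd$i == i & vd$j == j), ok,
                       info = sprintf("delete %d-%d", i, j))
        } else {
          ok <- oracle_is_chordal(add_edge_(g, i, j))
          expect_equal(any(vi$i == i & vi$j == j), ok,
                       info = sprintf("insert %d-%d", i, j))
        }
      }
    }
    # incremental update equals rebuild for every admissible move
    mvs <- rbind(vi, vd)
    for (r in seq_len(nrow(mvs))) {
      mv <- mvs[r, ]
      g2 <- if (mv$kind == "insert") add_edge_(g, mv$i, mv$j) else
        drop_edge_(g, mv$i, mv$j)
      ta <- apply_move(tr, mv)
      tb <- clique_tree(g2)
      expect_equal(ta$cliques, tb$cliques)
      expect_equal(separator_multiset(ta), separator_multiset(tb))
    }
  }
})

test_that("a chordal graph stores at most d maximal cliques", {
  set.seed(7)
  for (rep in 1:10) {
    g <- random_chordal_walk(7, steps = 12)
    expect_lte(length(maximal_cliques(g)), g$d)
  }
})

test_that("separator multiset is conserved through an insertion (modulo absorption)", {
  # non-trivial insert with no absorption: two triangles sharing an edge
  g <- ug(5, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(3, 5), c(4, 5)))
  tr <- clique_tree(g)
  vi <- valid_insertions(g, tr)
  mv <- vi[vi$i == 2 & vi$j == 4, ]
  skip_if(nrow(mv) == 0L)
  S <- mv$S[[1]]
  after <- apply_move(tr, mv)
  before_ms <- separator_multiset(tr)
  after_ms <- separator_multiset(after)
  gained <- c(paste(sort(c(S, mv$i)), collapse = ","),
              paste(sort(c(S, mv$j)), collapse = ","))
  lost <- paste(S, collapse = ",")
  expect_equal(sort(c(setdiff_multi(after_ms, before_ms))), sort(gained))
  expect_true(lost %in% setdiff_multi(before_ms, after_ms))
})

test_that("graph TSV and clique-tree JSON round-trip", {
  g <- ug(5, rbind(c(1, 2), c(2, 3), c(4, 5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, path)
  g2 <- read_graph_tsv(path, d = 5)
  expect_equal(g2$edges, g$edges)
  js <- jsonlite::fromJSON(clique_tree_json(clique_tree(g)),
                           simplifyVector = FALSE)
  expect_equal(length(js$cliques), 3L)
  expect_equal(length(js$tree_edges), 2L)
})
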