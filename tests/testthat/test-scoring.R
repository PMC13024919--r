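# a provider with a prescribed psi functional, for arithmetic checks
stub_provider <- function(psi_fun, n_eff, penalty = "quadratic",
                          penalized = TRUE) {
  kappa <- function(A) {
    pen <- if (penalized) {
      (log(n_eff) / 2) * decopula:::lambda_size(A, penalty)
    } else 0
    n_eff * psi_fun(A) - pen
  }
  list(kappa = kappa, psi = psi_fun, cache_stats = function() c(0, 0))
}

test_that("kappa combines fit and penalty with the documented arithmetic", {
  prov <- stub_provider(function(A) if (length(A) == 2) 0.5 else 0, 1000)
  expect_equal(prov$kappa(integer(0)), 0)
  expect_equal(prov$kappa(c(1, 2)), 500 - 3 * log(1000) / 2,
               tolerance = 1e-12)
  expect_equal(prov$kappa(1), -log(1000) / 2, tolerance = 1e-12)
})

test_that("global score expands to the clique-minus-separator sum", {
  psi <- function(A) 0.1 * length(A)^2
  prov <- stub_provider(psi, 100)
  chain <- ug(3, rbind(c(1, 2), c(2, 3)))
  tr <- clique_tree(chain)
  expect_equal(global_score(tr, prov),
               prov$kappa(c(1, 2)) + prov$kappa(c(2, 3)) - prov$kappa(2))
  empty <- clique_tree(ug(4))
  expect_equal(global_score(empty, prov), 4 * prov$kappa(1))
  pair <- clique_tree(ug(2, rbind(c(1, 2))))
  expect_equal(global_score(pair, prov), prov$kappa(c(1, 2)))
})

test_that("move deltas equal global score differences (local-update identity)", {
  set.seed(71)
  psi_vals <- new.env()
  psi <- function(A) {
    if (!length(A)) return(0)
    key <- paste(sort(A), collapse = ",")
    if (is.null(psi_vals[[key]])) psi_vals[[key]] <- runif(1)
    psi_vals[[key]]
  }
  prov <- stub_provider(psi, 500)
  for (rep in 1:10) {
    g <- random_chordal_walk(6, steps = 6)
    tr <- clique_tree(g)
    mvs <- rbind(valid_insertions(g, tr), valid_deletions(g, tr))
    for (r in seq_len(nrow(mvs))) {
      mv <- mvs[r, ]
      g2 <- if (mv$kind == "insert") add_edge_(g, mv$i, mv$j) else
        drop_edge_(g, mv$i, mv$j)
      delta <- delta_move(mv, prov)
      diff <- global_score(clique_tree(g2), prov) - global_score(tr, prov)
      expect_equal(delta, diff, tolerance = 1e-8)
    }
  }
})

test_that("independence makes every insertion delta the pure penalty term", {
  # psi additive over variables (here: zero) means the fit terms cancel and
  # delta reduces to -(log n / 2) * (lambda({i,j}) - 2 lambda({i}))
  prov <- stub_provider(function(A) 0, 1000)
  g <- ug(4)
  vi <- valid_insertions(g, clique_tree(g))
  deltas <- vapply(seq_len(nrow(vi)),
                   function(r) delta_move(vi[r, ], prov), numeric(1))
  expect_true(all(deltas < 0))
  expect_equal(unique(round(deltas, 10)),
               round(-(log(1000) / 2) * (3 - 1 - 1), 10))
})

test_that("a strongly dependent pair yields a positive insertion delta", {
  set.seed(81)
  n <- 1000
  X <- rgauss_copula2(n, 0.95)
  cfg <- estimator_config()
  th <- select_bandwidth(decopula:::probit_pseudo(X, cfg$epsilon), cfg)
  pobs <- pseudo_observations(X, make_folds(n, cfg$k, 1), cfg$epsilon)
  prov <- cbic_provider(pobs, th, score_config("cbic", n_eff = n))
  g <- ug(2)
  vi <- valid_insertions(g, clique_tree(g))
  expect_gt(delta_move(vi[1, ], prov), 0)
})

test_that("score cache returns identical values and never changes decisions", {
  set.seed(91)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  cfg <- estimator_config()
  th <- select_bandwidth(decopula:::probit_pseudo(X, cfg$epsilon), cfg)
  pobs <- pseudo_observations(X, make_folds(n, cfg$k, 1), cfg$epsilon)
  scfg <- score_config("cbic", n_eff = n)
  prov <- cbic_provider(pobs, th, scfg)
  v1 <- prov$kappa(c(1, 3))
  v2 <- prov$kappa(c(3, 1)) # canonical key: cache hit
  expect_identical(v1, v2)
  expect_equal(unname(prov$cache_stats()["hits"]), 1L)
  # an uncached provider recomputes to the last bit
  prov2 <- cbic_provider(pobs, th, scfg)
  expect_identical(prov2$kappa(c(1, 3)), v1)
})

test_that("raw-scale KDE functional approaches the normal differential entropy", {
  set.seed(95)
  n <- 4000
  X <- matrix(rnorm(n * 2), n, 2)
  cfg <- estimator_config()
  th <- select_bandwidth(scale(X), cfg)
  folds <- make_folds(n, cfg$k, 1)
  prov <- ngll_provider(X, folds, th, score_config("ng_ll", n_eff = n))
  # mean out-of-fold log density of a N(0,1) variable: -(1/2) log(2*pi*e)
  expect_lt(abs(prov$psi(1L) - (-0.5 * log(2 * pi * exp(1)))), 0.05)
})

test_that("the raw-scale score changes under monotone transforms, the copula score does not", {
  set.seed(99)
  n <- 400
  X <- rgauss_copula2(n, 0.7)
  Xt <- cbind(qexp(pnorm(X[, 1])), X[, 2])
  cfg <- estimator_config()
  folds <- make_folds(n, cfg$k, 1)

  thr <- select_bandwidth(scale(X), cfg)
  thr_t <- select_bandwidth(scale(Xt), cfg)
  pr <- ngll_provider(X, folds, thr, score_config("ng_ll", n_eff = n))
  pr_t <- ngll_provider(Xt, folds, thr_t, score_config("ng_ll", n_eff = n))
  tr <- clique_tree(ug(2, rbind(c(1, 2))))
  expect_false(isTRUE(all.equal(global_score(tr, pr),
                                global_score(tr, pr_t))))

  thc <- select_bandwidth(decopula:::probit_pseudo(X, cfg$epsilon), cfg)
  thc_t <- select_bandwidth(decopula:::probit_pseudo(Xt, cfg$epsilon), cfg)
  pc <- cbic_provider(pseudo_observations(X, folds, cfg$epsilon), thc,
                      score_config("cbic", n_eff = n))
  pc_t <- cbic_provider(pseudo_observations(Xt, folds, cfg$epsilon), thc_t,
                        score_config("cbic", n_eff = n))
  expect_identical(global_score(tr, pc), global_score(tr, pc_t))
})
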