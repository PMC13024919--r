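#' Run the synthetic recovery benchmark
#'
#' Orchestrates the full protocol per seed: simulate a chordal ground truth
#' and Gaussian-copula data, split rows 70/30 into training and test,
#' select the bandwidth and estimate all subset functionals on the training
#' rows only, learn a structure per method and marginal family, and compare
#' the result with the truth. Returns one tidy row per
#' (method, marginal, seed).
#'
#' The copula-information learner depends only on within-fold ranks, and
#' the marginal families are strictly increasing transforms of one shared
#' uniform matrix, so its learned graph is identical across families within
#' a seed; it is learned once per seed and its row is replicated per family.
#' The raw-scale likelihood baseline is rerun on every family's data.
#'
#' The test split takes no part in learning; it is used only for the
#' informational held-out predictive log-score column.
#'
#' @param d,n,rho,nu Benchmark dimensions; see [simulate_benchmark()].
#' @param seeds Integer vector of seeds (one simulated dataset each).
#' @param methods Subset of `c("cbic", "ng_ll")`.
#' @param marginals Subset of `c("normal", "exponential", "beta")`.
#' @param train_frac Training fraction of the 70/30-style split.
#' @param config An [estimator_config()]; its `fold_seed` is re-derived per
#'   seed.
#' @param max_iter Optional iteration cap passed to [learn_structure()].
#' @param verbose Print per-run progress.
#' @return A tibble with columns `method`, `marginal`, `seed`, the
#'   [graph_recovery()] metrics, `n_edges_truth`, `n_edges_learned`,
#'   `time_s`, and `test_logscore`.
#' @export
run_benchmark <- function(d = 30, n = 2000, rho = 0.1, nu = 1,
                          seeds = 0:19, methods = c("cbic", "ng_ll"),
                          marginals = c("normal", "exponential", "beta"),
                          train_frac = 0.7,
                          config = estimator_config(),
                          max_iter = NULL, verbose = FALSE) {
  methods <- match.arg(methods, c("cbic", "ng_ll"), several.ok = TRUE)
  marginals <- match.arg(marginals,
                         c("normal", "exponential", "beta"),
                         several.ok = TRUE)
  rows <- list()
  failures <- 0L
  for (seed in seeds) {
    res <- tryCatch(
      benchmark_one_seed(d, n, rho, nu, seed, methods, marginals,
                         train_frac, config, max_iter, verbose),
      error = function(e) {
        warning(sprintf("seed %d failed: %s", seed, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) failures <- failures + 1L else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- failures
  out
}

benchmark_one_seed <- function(d, n, rho, nu, seed, methods, marginals,
                               train_frac, config, max_iter, verbose) {
  sim <- simulate_benchmark(d, n, rho, nu, seed, marginals)
  n_train <- round(train_frac * n)
  train_idx <- withr::with_seed(seed + 2L, sample(n, n_train))
  cfg <- config
  cfg$fold_seed <- seed + 3L
  truth <- sim$truth
  out <- list()
  for (method in methods) {
    fams <- if (method == "cbic") marginals[1L] else marginals
    for (fam in fams) {
      X_tr <- sim$X[[fam]][train_idx, , drop = FALSE]
      X_te <- sim$X[[fam]][-train_idx, , drop = FALSE]
      t0 <- proc.time()[["elapsed"]]
      fit <- learn_structure(X_tr, score = method, config = cfg,
                             max_iter = max_iter)
      elapsed <- proc.time()[["elapsed"]] - t0
      rec <- graph_recovery(truth, fit$graph)
      ts <- holdout_logscore(fit, X_tr, X_te, cfg)
      rep_fams <- if (method == "cbic") marginals else fam
      for (f2 in rep_fams) {
        out[[length(out) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(method = method, marginal = f2, seed = seed),
          rec,
          tibble::tibble(n_edges_truth = nrow(truth$edges),
                         n_edges_learned = nrow(fit$graph$edges),
                         time_s = elapsed, test_logscore = ts))
      }
      if (verbose) {
        message(sprintf("seed %d %s/%s: F1=%.3f SHD=%d (%.1fs)",
                        seed, method, fam, rec$f1, rec$shd, elapsed))
      }
    }
  }
  dplyr::bind_rows(out)
}

# held-out predictive log-score of the fitted decomposable model: clique
# minus separator sums of mean log density on the test rows, with marginals
# fitted on the training rows (fit on train, transform test)
holdout_logscore <- function(fit, X_tr, X_te, config) {
  if (!nrow(X_te)) return(NA_real_)
  theta <- fit$theta$theta
  floor_log <- log(config$density_floor)
  if (fit$score_kind == "cbic") {
    Zc <- probit_pseudo(X_tr, config$epsilon)
    Zq <- probit_pseudo(X_tr, config$epsilon, X_new = X_te)
    term <- function(A) {
      if (!length(A)) return(0)
      q <- Zq[, A, drop = FALSE]
      lk <- cross_log_kde(q, Zc[, A, drop = FALSE], theta[A]) -
        rowSums(stats::dnorm(q, log = TRUE))
      mean(pmax(lk, floor_log))
    }
  } else {
    ctr <- scale(X_tr)
    qs <- scale(X_te, center = attr(ctr, "scaled:center"),
                scale = attr(ctr, "scaled:scale"))
    term <- function(A) {
      if (!length(A)) return(0)
      lk <- cross_log_kde(qs[, A, drop = FALSE], ctr[, A, drop = FALSE],
                          theta[A])
      mean(pmax(lk, floor_log))
    }
  }
  s <- sum(vapply(fit$tree$cliques, term, numeric(1)))
  if (length(fit$tree$separators)) {
    s <- s - sum(vapply(fit$tree$separators, term, numeric(1)))
  }
  s
}

#' Aggregate benchmark results
#'
#' Mean and standard deviation of each recovery metric per method and
#' marginal family, over the seeds present in the results.
#'
#' @param results A tibble from [run_benchmark()].
#' @return A tibble with one row per (method, marginal) and `mean_` / `sd_`
#'   columns for f1, precision, recall, shd and time.
#' @export
summarize_benchmark <- function(results) {
  results |>
    dplyr::group_by(.data$method, .data$marginal) |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      dplyr::across(c("f1", "precision", "recall", "shd", "time_s"),
                    list(mean = mean, sd = stats::sd),
                    .names = "{.fn}_{.col}"),
      .groups = "drop")
}
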