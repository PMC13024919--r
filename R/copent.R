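#' Estimator configuration
#'
#' Collects the tuning constants of the nonparametric copula-entropy
#' estimator. Defaults: `k = 5` folds (standard cross-validation choice;
#' for fixed k the difference from leave-one-out is asymptotically
#' negligible), `epsilon = 1e-5` (truncation of pseudo-observations into
#' `[epsilon, 1 - epsilon]`, far below `1/(m+1)` for any realistic fold size,
#' so it only guards exact-0/1 pathologies), `density_floor = 1e-100` (log
#' floor about -230, well below any sane density), and a bandwidth box
#' `[Var(Z_j)/beta_max, Var(Z_j)/beta_min]` with `beta_min = 1` and
#' `beta_max = n_tr^{2/5}` (lower bound at the optimal-rate scale, upper
#' bound at the data variance).
#'
#' @param k Fold count (integer, at least 2).
#' @param epsilon Truncation constant in (0, 1/2).
#' @param density_floor Positive density floor.
#' @param beta_min,beta_max Bandwidth box constants, `0 < beta_min <
#'   beta_max`; `beta_max = NULL` means `n_tr^{2/5}` at fit time.
#' @param max_iter Optimizer iteration cap.
#' @param rel_tol Relative objective tolerance for the optimizer.
#' @param fold_seed Seed for the fold assignment.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(k = 5L, epsilon = 1e-5, density_floor = 1e-100,
                             beta_min = 1, beta_max = NULL,
                             max_iter = 100L, rel_tol = 1e-8,
                             fold_seed = 1L) {
  stopifnot(k >= 2L, epsilon > 0, epsilon < 0.5, density_floor > 0,
            beta_min > 0, is.null(beta_max) || beta_max > beta_min)
  structure(list(k = as.integer(k), epsilon = epsilon,
                 density_floor = density_floor, beta_min = beta_min,
                 beta_max = beta_max, max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, fold_seed = as.integer(fold_seed)),
            class = "estimator_config")
}

#' Deterministic fold plan
#'
#' Partitions `1..n_tr` into `k` folds whose sizes differ by at most one.
#' The plan is a deterministic function of `(n_tr, k, seed)` and does not
#' disturb the global RNG state.
#'
#' @param n_tr Number of training rows.
#' @param k Fold count, `2 <= k <= n_tr`.
#' @param seed Integer seed.
#' @return An integer vector of fold labels in `1..k`, length `n_tr`.
#' @export
make_folds <- function(n_tr, k, seed = 1L) {
  stopifnot(k >= 2L, k <= n_tr)
  withr::with_seed(seed, sample(rep_len(seq_len(k), n_tr)))
}

#' Fold-wise pseudo-observations with probit transform
#'
#' For each fold `r`, the empirical marginal CDF is fitted on the
#' complementary rows `J_-r` and every row is mapped to
#' `clamp(epsilon, 1 - epsilon, m/(m+1) * Fhat(x))` with `m = |J_-r|`, then
#' through the probit `qnorm`. The construction depends only on within-fold
#' ranks, so strictly increasing per-column transforms of the data leave it
#' unchanged - the source of the score's marginal invariance.
#'
#' @param X Numeric training matrix (rows = observations).
#' @param folds Fold labels from [make_folds()].
#' @param epsilon Truncation constant.
#' @return An object of class `pseudo_obs`: per fold, the probit matrix `Z`
#'   (all training rows under that fold's marginals), held-out row indices
#'   `test_rows`, and fitting rows `train_rows`.
#' @export
pseudo_observations <- function(X, folds, epsilon = 1e-5) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("data matrix must be finite")
  n <- nrow(X); d <- ncol(X)
  stopifnot(length(folds) == n)
  k <- max(folds)
  Zs <- vector("list", k)
  train_rows <- vector("list", k)
  test_rows <- vector("list", k)
  for (r in seq_len(k)) {
    te <- which(folds == r)
    tr <- which(folds != r)
    m <- length(tr)
    U <- matrix(0, n, d)
    for (col in seq_len(d)) {
      Fhat <- stats::ecdf(X[tr, col])
      U[, col] <- pmin(1 - epsilon,
                       pmax(epsilon, (m / (m + 1)) * Fhat(X[, col])))
    }
    Zs[[r]] <- stats::qnorm(U)
    train_rows[[r]] <- tr
    test_rows[[r]] <- te
  }
  structure(list(Z = Zs, train_rows = train_rows, test_rows = test_rows,
                 folds = folds, k = k, n_tr = n, d = d, epsilon = epsilon),
            class = "pseudo_obs")
}

# full-training pseudo-observations (self-inclusive ECDF), probit scale;
# used for bandwidth selection and held-out transforms
probit_pseudo <- function(X, epsilon = 1e-5, X_new = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  target <- if (is.null(X_new)) X else as.matrix(X_new)
  U <- matrix(0, nrow(target), d)
  for (col in seq_len(d)) {
    Fhat <- stats::ecdf(X[, col])
    U[, col] <- pmin(1 - epsilon,
                     pmax(epsilon, (n / (n + 1)) * Fhat(target[, col])))
  }
  stats::qnorm(U)
}

#' Select the global diagonal bandwidth
#'
#' Maximizes the leave-one-out cross-validated predictive log-score of a
#' diagonal Gaussian kernel density estimate on the full d-dimensional
#' sample `Z`, over log-bandwidths `xi = log(theta)` inside the box
#' `[log(Var(Z_j)/beta_max), log(Var(Z_j)/beta_min)]`, using box-constrained
#' quasi-Newton (L-BFGS-B) with an analytic gradient. The selected vector is
#' computed once before structure search and kept fixed; every subset `A`
#' uses the coordinate projection `theta[A]`.
#'
#' @param Z Numeric matrix (probit pseudo-observations for the copula score;
#'   standardized raw data for the raw-scale baseline).
#' @param config An [estimator_config()].
#' @return An object of class `bandwidth`: `theta` (per-dimension kernel
#'   variances), `xi`, the attained objective `value`, and `convergence`.
#' @export
select_bandwidth <- function(Z, config = estimator_config()) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  stopifnot(n >= 3L)
  beta_max <- if (is.null(config$beta_max)) n^(2 / 5) else config$beta_max
  v <- apply(Z, 2L, stats::var)
  lower <- log(v / beta_max)
  upper <- log(v / config$beta_min)
  xi0 <- (lower + upper) / 2
  fn <- function(xi) loo_kde_objective(Z, exp(xi))$value
  gr <- function(xi) loo_kde_objective(Z, exp(xi))$grad
  fit <- tryCatch(
    stats::optim(xi0, fn, gr, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(fnscale = -1, maxit = config$max_iter,
                                factr = config$rel_tol / .Machine$double.eps)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    warning("bandwidth optimization failed; falling back to the box midpoint")
    fit <- list(par = xi0, value = fn(xi0), convergence = NA_integer_)
  }
  structure(list(theta = exp(fit$par), xi = fit$par, value = fit$value,
                 convergence = fit$convergence, lower = lower, upper = upper),
            class = "bandwidth")
}

#' Log copula density via probit-transformed KDE
#'
#' Evaluates the log of the probit-KDE copula density estimate at points of
#' the open unit hypercube: a diagonal Gaussian KDE on the probit scale,
#' divided by the Jacobian `prod(phi(z_i))`, computed with the log-sum-exp
#' identity and clamped below at `log(density_floor)`.
#'
#' @param u Numeric matrix of evaluation points in `(0, 1)^|A|` (rows =
#'   points).
#' @param centers_z Probit-transformed kernel centers (rows = training
#'   points, columns matching `u`).
#' @param theta Positive bandwidth variances for the involved coordinates.
#' @param density_floor Lower clamp on the density.
#' @return A numeric vector of log-density values (finite under the floor).
#' @export
log_copula_density <- function(u, centers_z, theta,
                               density_floor = 1e-100) {
  u <- as.matrix(u)
  if (any(u <= 0) || any(u >= 1)) stop("u must lie strictly inside (0,1)")
  z <- stats::qnorm(u)
  lk <- as.numeric(cross_log_kde(z, as.matrix(centers_z), theta))
  out <- lk - rowSums(stats::dnorm(z, log = TRUE))
  pmax(out, log(density_floor))
}

#' Out-of-fold copula information estimate for a variable subset
#'
#' Computes the average predictive log copula density over all training
#' points: each fold's held-out rows are scored under the copula density
#' fitted from that fold's complementary rows (marginals and kernel centers
#' alike), so no information leaks from scored points into the fit. The
#' empty set returns 0 (the copula of no variables is degenerate with zero
#' entropy); large positive values indicate strong dependence within `A`.
#'
#' @param A Integer vector of column indices (possibly empty).
#' @param pobs A [pseudo_observations()] object.
#' @param theta Global bandwidth vector (full length `d`); the projection
#'   `theta[A]` is used.
#' @param density_floor Lower clamp on the per-point density.
#' @return A scalar estimate of `E[log c_A(U_A)]` (non-negative in
#'   population; finite by construction).
#' @export
psi_kde <- function(A, pobs, theta, density_floor = 1e-100) {
  A <- sort(as.integer(A))
  if (length(A) == 0L) return(0)
  if (inherits(theta, "bandwidth")) theta <- theta$theta
  total <- 0
  for (r in seq_len(pobs$k)) {
    Zr <- pobs$Z[[r]]
    q <- Zr[pobs$test_rows[[r]], A, drop = FALSE]
    ctr <- Zr[pobs$train_rows[[r]], A, drop = FALSE]
    lk <- cross_log_kde(q, ctr, theta[A])
    lc <- lk - rowSums(stats::dnorm(q, log = TRUE))
    total <- total + sum(pmax(lc, log(density_floor)))
  }
  total / pobs$n_tr
}
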