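## R surface of the constrained bilinear lasso: single solve, multi-start,
## cross-validated lambda, coefficient post-processing and the theoretical
## L1 estimation error bound.

#' Solve the structured lasso at one regularization value
#'
#' Minimizes `(1/n) sum_i (y_i - alpha' X_i beta)^2 + lambda * ||beta||_1`
#' subject to `||alpha||_1 = 1` and the sign of the largest-magnitude
#' component of beta being positive, by alternating minimization. The
#' beta-step (alpha fixed) is a coordinate-descent lasso. The alpha-step
#' profiles the constrained objective over the scale-equivalence class
#' `(alpha/s, beta*s)`: with beta fixed it minimizes
#' `(1/n)||y - V alpha||^2 + lambda * ||beta||_1 * ||alpha||_1`, where the L1
#' term arises purely from the unit-norm reparametrization -- the row effects
#' themselves carry no regularization. Each iteration ends by renormalizing
#' to `||alpha||_1 = 1`, which changes neither the fit nor the penalty value,
#' so the objective is non-increasing across iterations.
#'
#' @param X standardized design array, G x q x n.
#' @param y centered outcomes, length n.
#' @param lambda regularization value (>= 0).
#' @param init list with numeric `alpha` (length G) and `beta` (length q).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter cap on alternating iterations.
#' @return A `clusso_solution`: `alpha`, `beta`, `lambda`, `objective`,
#'   `n_iter`, `converged`, and `trace` (objective value per iteration).
#' @export
solve_structured_lasso <- function(X, y, lambda, init, tol = 1e-6, max_iter = 200L) {
  stopifnot(length(dim(X)) == 3, lambda >= 0)
  fit <- solve_single_cpp(X, y, lambda, init$alpha, init$beta,
                          tol, as.integer(max_iter), 1e-9, 1000L)
  fit$alpha <- as.numeric(fit$alpha)
  fit$beta <- as.numeric(fit$beta)
  structure(c(fit, list(lambda = lambda)), class = "clusso_solution")
}

## random starting point: alpha standard normal then L1-normalized, beta standard normal
random_init <- function(G, q) {
  a <- rnorm(G)
  while (sum(abs(a)) < 1e-12) a <- rnorm(G)
  list(alpha = a / sum(abs(a)), beta = rnorm(q))
}

#' Solve the structured lasso from several random initializations
#'
#' The alternating algorithm converges to a stationary point rather than the
#' global minimizer, so the solve is repeated from `n_inits` random starts and
#' the solution with the smallest objective is returned. Deterministic given
#' `seed`.
#'
#' @inheritParams solve_structured_lasso
#' @param n_inits number of random starts (default 5).
#' @param seed integer seed for the start draws.
#' @return The best `clusso_solution`, with `init_seed` recorded.
#' @export
solve_multi_init <- function(X, y, lambda, n_inits = 5L, seed = 1L,
                             tol = 1e-6, max_iter = 200L) {
  stopifnot(n_inits >= 1L)
  G <- dim(X)[1]; q <- dim(X)[2]
  inits <- withr::with_seed(seed, replicate(n_inits, random_init(G, q), simplify = FALSE))
  best <- NULL
  last_err <- NULL
  for (ini in inits) {
    sol <- tryCatch(solve_structured_lasso(X, y, lambda, ini, tol, max_iter),
                    error = function(e) e)
    if (inherits(sol, "error")) { last_err <- sol; next }
    if (is.null(best) || sol$objective < best$objective) best <- sol
  }
  if (is.null(best)) stop(last_err)
  best$init_seed <- as.integer(seed)
  best
}

#' Choose lambda by k-fold cross-validation
#'
#' Subjects are partitioned into `n_folds` folds by a seeded shuffle; for each
#' candidate lambda the mean held-out squared prediction error across folds is
#' computed, and the lambda minimizing it is returned (ties broken toward the
#' smaller lambda).
#'
#' @inheritParams solve_multi_init
#' @param lambda_grid non-empty numeric grid of candidate values.
#' @param n_folds number of folds (default 5).
#' @return List with `lambda` (the selected value) and `cv_table`
#'   (data.frame: `lambda`, `mse_mean`, `mse_sd`).
#' @export
cv_lambda <- function(X, y, lambda_grid, n_folds = 5L, seed = 1L, n_inits = 5L,
                      tol = 1e-6, max_iter = 200L) {
  if (!length(lambda_grid)) stop_clusso("lambda grid is empty")
  if (n_folds < 2L) stop_clusso("need at least 2 folds")
  n <- length(y)
  if (n < n_folds) stop_clusso("fewer subjects (%d) than folds (%d)", n, n_folds)
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  if (min(table(fold)) < 2L) stop_clusso("a fold has fewer than 2 subjects")
  lambda_grid <- sort(lambda_grid)
  mse <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    Xtr <- X[, , tr, drop = FALSE]; ytr <- y[tr]
    Xte <- X[, , !tr, drop = FALSE]; yte <- y[!tr]
    for (l in seq_along(lambda_grid)) {
      sol <- solve_multi_init(Xtr, ytr, lambda_grid[l], n_inits,
                              seed = derive_seed(seed, f, l), tol = tol, max_iter = max_iter)
      pred <- predict_bilinear(sol$alpha, sol$beta, Xte)
      mse[f, l] <- mean((yte - pred)^2)
    }
  }
  cv_table <- data.frame(lambda = lambda_grid,
                         mse_mean = colMeans(mse),
                         mse_sd = apply(mse, 2, sd))
  best <- which(cv_table$mse_mean == min(cv_table$mse_mean))[1]  # ties -> smaller lambda
  list(lambda = lambda_grid[best], cv_table = cv_table)
}

## fitted values alpha' X_i beta for a design array
predict_bilinear <- function(alpha, beta, X) {
  n <- dim(X)[3]
  G <- dim(X)[1]; q <- dim(X)[2]
  vapply(seq_len(n), function(i) {
    sum(alpha * (matrix(X[, , i], G, q) %*% beta))
  }, numeric(1))
}

#' L1-normalize a coefficient vector and zero out negligible components
#'
#' Divides beta by its L1 norm (if nonzero) and sets components with magnitude
#' below `threshold` to zero. The result is deliberately not renormalized
#' after zeroing.
#'
#' @param beta numeric coefficient vector.
#' @param threshold magnitude threshold (default 0.001).
#' @return The normalized, thresholded vector.
#' @export
normalize_threshold <- function(beta, threshold = 0.001) {
  if (threshold < 0) stop_clusso("threshold must be >= 0")
  s <- sum(abs(beta))
  if (s > 0) beta <- beta / s
  beta[abs(beta) < threshold] <- 0
  beta
}

#' Theoretical L1 estimation error bound for the structured lasso
#'
#' Computes the oracle regularization level
#' `lambda_n = (1 + delta0) * sigma * sqrt(2 * (1 + a) * log(G * q) / n)` and
#' the coefficient error bound
#' `B0 * lambda_n * s0 * (1 + 2 * ||beta_star||_1 / beta_max)` with
#' `B0 = 4 * kappa2`, where `kappa2` is the structured restricted-eigenvalue
#' constant, `s0` the support size of `beta_star (x) alpha_star`, and
#' `beta_max` the largest-magnitude component of `beta_star`.
#'
#' @param delta0,a positive slack constants.
#' @param sigma outcome noise standard deviation.
#' @param G,q,n design dimensions and sample size.
#' @param kappa2 restricted-eigenvalue constant (> 0).
#' @param s0 support size of the Kronecker coefficient vector.
#' @param beta_star true column-effect vector (not identically zero).
#' @return List with `lambda_n` and `l1_bound`.
#' @export
theoretical_bound <- function(delta0, a, sigma, G, q, n, kappa2, s0, beta_star) {
  stopifnot(delta0 > 0, a > 0, sigma > 0, G >= 1, q >= 1, n >= 1, kappa2 > 0,
            s0 >= 0, s0 <= G * q)
  if (all(beta_star == 0)) stop_clusso("beta_star must not be identically zero")
  beta_max <- abs(beta_star[which_max_abs(beta_star)])
  lambda_n <- (1 + delta0) * sigma * sqrt(2 * (1 + a) * log(G * q) / n)
  B0 <- 4 * kappa2
  list(lambda_n = lambda_n,
       l1_bound = B0 * lambda_n * s0 * (1 + 2 * sum(abs(beta_star)) / beta_max))
}

#' @export
print.clusso_solution <- function(x, ...) {
  cat(sprintf("Structured lasso solution (lambda = %g): objective %.6g after %d iterations%s\n",
              x$lambda, x$objective, x$n_iter,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  cat("alpha:", paste(signif(x$alpha, 4), collapse = " "), "\n")
  cat("beta: ", paste(signif(x$beta, 4), collapse = " "), "\n")
  invisible(x)
}
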