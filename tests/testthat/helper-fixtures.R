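## Shared fixtures, built in code at test time.

## three-subject toy tubule table with q = 2 features
toy_tubules <- function() {
  tubule_table(data.frame(
    subject_id = c("A", "A", "A", "B", "B", "C", "C"),
    object_id = c("t1", "t2", "t3", "t1", "t2", "t1", "t2"),
    area = c(1, 3, 10, 2, 4, 5, 7),
    thickness = c(3, 5, 20, 1, 2, 6, 8)))
}

toy_outcomes <- function(ids = c("A", "B", "C")) {
  data.frame(subject_id = ids, y = seq_along(ids) * 1.5)
}

write_toy_csvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tf <- file.path(dir, "tubules.csv")
  of <- file.path(dir, "outcomes.csv")
  write.csv(as.data.frame(toy_tubules()), tf, row.names = FALSE)
  write.csv(toy_outcomes(), of, row.names = FALSE)
  list(tubules = tf, outcomes = of)
}

## small random structured-lasso instance (standardized-scale design)
random_instance <- function(n, G, q, seed, noise = 1) {
  withr::with_seed(seed, {
    X <- array(rnorm(G * q * n), c(G, q, n))
    alpha <- rnorm(G); alpha <- alpha / sum(abs(alpha))
    beta <- rnorm(q)
    y <- vapply(seq_len(n), function(i) sum(alpha * (matrix(X[, , i], G, q) %*% beta)),
                numeric(1)) + rnorm(n, 0, noise)
    list(X = X, y = y, alpha = alpha, beta = beta)
  })
}

## Brute-force grid oracle for the G = 2 structured lasso: walk the L1 sphere
## alpha = (t, s * (1 - |t|)), solve the convex lasso in beta at each alpha
## with glmnet (independent of the package's alternating solver), and return
## the smallest objective found. A refinement pass around the coarse winner
## sharpens the grid.
grid_oracle_objective <- function(X, y, lambda, step = 1e-3, refine_step = 1e-5) {
  n <- length(y)
  obj_at <- function(t, s) {
    alpha <- c(t, s * (1 - abs(t)))
    Z <- t(vapply(seq_len(n), function(i) as.numeric(t(X[, , i]) %*% alpha),
                  numeric(dim(X)[2])))
    if (sum(abs(alpha)) < 1e-12) return(Inf)
    fit <- glmnet::glmnet(Z, y, lambda = lambda / 2, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-12)
    beta <- as.numeric(fit$beta)
    mean((y - Z %*% beta)^2) + lambda * sum(abs(beta))
  }
  grid <- seq(-1, 1, by = step)
  best <- Inf; best_t <- NA; best_s <- NA
  for (s in c(1, -1)) {
    vals <- vapply(grid, obj_at, numeric(1), s = s)
    i <- which.min(vals)
    if (vals[i] < best) { best <- vals[i]; best_t <- grid[i]; best_s <- s }
  }
  fine <- seq(max(-1, best_t - step), min(1, best_t + step), by = refine_step)
  min(best, min(vapply(fine, obj_at, numeric(1), s = best_s)))
}

## fitted values straight from a solution's coefficients
predict_check <- function(sol, X) {
  vapply(seq_len(dim(X)[3]),
         function(i) sum(sol$alpha * (matrix(X[, , i], dim(X)[1], dim(X)[2]) %*% sol$beta)),
         numeric(1))
}

## shared truth used by several generator-based tests
test_truth <- function(q = 10, s_beta = 0.8, G = 2, seed = 11) {
  generate_truth(q, s_beta, G, seed = seed)
}
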