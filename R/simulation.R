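## Synthetic data generators for the supported simulation scenarios, the
## selection/prediction performance metrics, and the replication harness.

#' Sample per-subject object counts from a moment-matched discrete uniform
#'
#' Counts are drawn i.i.d. from the discrete uniform distribution on
#' `{a, a+1, ..., b}` with `H` support points, where `H` is the largest odd
#' integer at most `sqrt(12 * sigma2_M + 1)` (which matches the target
#' variance as closely as a symmetric discrete uniform allows) and
#' `a = mu_M - (H - 1)/2`, `b = mu_M + (H - 1)/2` (matching the mean).
#'
#' @param n number of subjects.
#' @param mu_M target mean object count (default 40).
#' @param sigma2_M target variance of the object count (default 5).
#' @param seed integer seed.
#' @return Integer vector of length `n`.
#' @export
sample_tubule_counts <- function(n, mu_M = 40, sigma2_M = 5, seed = 1L) {
  H <- floor(sqrt(12 * sigma2_M + 1))
  if (H %% 2 == 0) H <- H - 1
  H <- max(H, 1)
  a <- mu_M - (H - 1) / 2
  b <- mu_M + (H - 1) / 2
  if (a < 1) stop_clusso("mean object count %g too small for variance %g (support would start at %g)",
                         mu_M, sigma2_M, a)
  support <- seq(a, b)
  if (length(support) == 1L) return(rep(as.integer(a), n))
  withr::with_seed(seed, as.integer(sample(support, n, replace = TRUE)))
}

#' Draw the shared true coefficient vectors
#'
#' Entries of both the row effects and the column effects are drawn uniformly
#' from `{1, 2, 3, 4}`; sparsity is then invoked by zeroing
#' `round(s_beta * q)` positions of beta chosen without replacement. The draw
#' is deterministic given `seed` so one truth can be shared across all
#' simulation settings and repetitions.
#'
#' @param q number of features.
#' @param s_beta proportion of beta set to zero.
#' @param G_true number of latent subgroups (length of alpha).
#' @param seed integer seed.
#' @return List with `alpha_star` (length `G_true`) and `beta_star` (length `q`).
#' @export
generate_truth <- function(q, s_beta, G_true = 2L, seed = 1L) {
  stopifnot(q >= 1, s_beta >= 0, s_beta <= 1, G_true >= 1)
  withr::with_seed(seed, {
    alpha <- sample(1:4, G_true, replace = TRUE)
    beta <- sample(1:4, q, replace = TRUE)
    n_zero <- round(s_beta * q)
    if (n_zero > 0) beta[sample.int(q, n_zero)] <- 0
    list(alpha_star = as.numeric(alpha), beta_star = as.numeric(beta))
  })
}

## scenario -> number of latent subgroups
scenario_G <- function(scenario) {
  switch(scenario, two_cluster = 2L, correlated = 2L, three_cluster = 3L,
         one_cluster = 1L, stop_clusso("unknown scenario '%s'", scenario))
}

#' Row covariance implied tubule correlation (correlated scenario)
#'
#' The correlation between the two latent cluster rows implied by a 2 x 2 row
#' covariance matrix, `Sigma_r[1,2] / sqrt(Sigma_r[1,1] * Sigma_r[2,2])`.
#' With the default `Sigma_r = [[1, sqrt(3)/2], [sqrt(3)/2, 3]]` this is
#' exactly 0.5.
#'
#' @param Sigma_r 2 x 2 row covariance matrix.
#' @return The implied correlation.
#' @export
row_covariance_correlation <- function(Sigma_r = default_sigma_r()) {
  Sigma_r[1, 2] / sqrt(Sigma_r[1, 1] * Sigma_r[2, 2])
}

#' Default row covariance of the correlated-tubule scenario
#' @return The 2 x 2 matrix `[[1, sqrt(3)/2], [sqrt(3)/2, 3]]`.
#' @export
default_sigma_r <- function() {
  matrix(c(1, sqrt(3) / 2, sqrt(3) / 2, 3), 2, 2)
}

#' Generate one synthetic dataset
#'
#' Emulates the generative structure of the simulation study: per subject a
#' latent cluster-mean matrix X* (rows drawn per scenario), cluster
#' proportions w drawn uniformly from a finite set, outcome
#' `y = alpha' diag(w) X* beta + eps` with `eps ~ N(0, sigma2_eps)`, and an
#' observed ragged object table built by resampling latent rows with
#' probabilities w and adding Gaussian measurement error with variance
#' `sigma2_R`. Throughout, `N(a, b)` means mean `a` and variance `b`.
#'
#' Scenarios: `two_cluster` (rows N(2,1) and N(5,3), w1 uniform on
#' {0.2, 0.3, ..., 0.8}); `correlated` (matrix normal with row means 2 and 5,
#' row covariance [default_sigma_r()], identity column covariance);
#' `three_cluster` (rows N(2,1), N(5,3), N(7,3); w1 in {0.2,...,0.6}, w2 in
#' {0.2,...,0.8 - w1}, w3 the remainder); `one_cluster` (a single latent row
#' with entries N(2,3)).
#'
#' @param n number of subjects.
#' @param q number of features.
#' @param truth list from [generate_truth()]; its `alpha_star` length must
#'   equal the scenario's number of subgroups.
#' @param scenario one of `"two_cluster"`, `"correlated"`, `"three_cluster"`,
#'   `"one_cluster"`.
#' @param sigma2_eps outcome noise variance (default 1).
#' @param sigma2_R measurement (resampling) error variance (default 1).
#' @param mu_M,sigma2_M object-count mean and variance (defaults 40 and 5).
#' @param seed integer seed; fixes every byte of the output.
#' @return List with `tubules` (a [tubule_table()]), `outcomes`
#'   (subject_id, y), `truth` (a `clusso_truth`: `subjects`, `alpha_star`,
#'   `beta_star`, `w`, `X_star`, `X_dstar`, `y`), and `true_labels` (integer
#'   latent subgroup per object row, aligned to `tubules`).
#' @export
generate_dataset <- function(n, q, truth, scenario = "two_cluster",
                             sigma2_eps = 1, sigma2_R = 1,
                             mu_M = 40, sigma2_M = 5, seed = 1L) {
  G <- scenario_G(scenario)
  if (length(truth$alpha_star) != G) {
    stop_clusso("truth has %d row effects but scenario '%s' has %d subgroups",
                length(truth$alpha_star), scenario, G)
  }
  if (length(truth$beta_star) != q) stop_clusso("truth beta length != q")
  p <- sample_tubule_counts(n, mu_M, sigma2_M, seed = derive_seed(seed, 1L))
  wd <- 6 # enough id digits for any n used here
  subjects <- sprintf(paste0("S%0", wd, "d"), seq_len(n))

  withr::with_seed(derive_seed(seed, 2L), {
    X_star <- array(0, c(G, q, n))
    w <- matrix(0, n, G)
    if (scenario == "correlated") {
      A <- t(chol(default_sigma_r()))
      mu <- matrix(c(2, 5), G, q)
    }
    for (i in seq_len(n)) {
      X_star[, , i] <- switch(scenario,
        two_cluster = rbind(rnorm(q, 2, 1), rnorm(q, 5, sqrt(3))),
        correlated = mu + A %*% matrix(rnorm(2 * q), 2, q),
        three_cluster = rbind(rnorm(q, 2, 1), rnorm(q, 5, sqrt(3)), rnorm(q, 7, sqrt(3))),
        one_cluster = matrix(rnorm(q, 2, sqrt(3)), 1, q))
      w[i, ] <- switch(scenario,
        two_cluster = , correlated = {
          w1 <- sample(seq(0.2, 0.8, by = 0.1), 1)
          c(w1, 1 - w1)
        },
        three_cluster = {
          w1 <- sample(seq(0.2, 0.6, by = 0.1), 1)
          w2 <- sample(seq(0.2, 0.8 - w1, by = 0.1), 1)
          c(w1, w2, 1 - w1 - w2)
        },
        one_cluster = 1)
    }
    X_dstar <- sweep_rows(X_star, w)
    y <- vapply(seq_len(n), function(i) {
      sum(truth$alpha_star * (matrix(X_dstar[, , i], G, q) %*% truth$beta_star))
    }, numeric(1)) + rnorm(n, 0, sqrt(sigma2_eps))

    ## observed ragged table: resample latent rows with prob w, add noise
    total <- sum(p)
    sub_idx <- rep.int(seq_len(n), p)
    labels <- integer(total)
    feats <- matrix(0, total, q)
    pos <- 0L
    for (i in seq_len(n)) {
      k <- if (G == 1L) rep(1L, p[i]) else sample.int(G, p[i], replace = TRUE, prob = w[i, ])
      Xi <- matrix(X_star[, , i], G, q)
      rows <- t(Xi)[, k, drop = FALSE]                                # q x p_i
      noise <- matrix(rnorm(p[i] * q, 0, sqrt(sigma2_R)), q, p[i])
      feats[pos + seq_len(p[i]), ] <- t(rows + noise)
      labels[pos + seq_len(p[i])] <- k
      pos <- pos + p[i]
    }
    fn <- paste0("f", seq_len(q))
    df <- data.frame(subject_id = subjects[sub_idx],
                     object_id = paste0("t", sequence(p)),
                     feats, stringsAsFactors = FALSE)
    names(df) <- c("subject_id", "object_id", fn)
    tubules <- tubule_table(df)
    list(tubules = tubules,
         outcomes = data.frame(subject_id = subjects, y = y, stringsAsFactors = FALSE),
         truth = structure(list(subjects = subjects, alpha_star = truth$alpha_star,
                                beta_star = truth$beta_star, w = w, X_star = X_star,
                                X_dstar = X_dstar, y = y, feature_names = fn,
                                scenario = scenario),
                           class = "clusso_truth"),
         true_labels = labels)
  })
}

#' Variable-selection metrics for a thresholded coefficient estimate
#'
#' TPR is the proportion of truly nonzero components identified as nonzero;
#' FPR the proportion of truly zero components identified as nonzero; the L1
#' bias is `|| |b_hat|/||b_hat||_1 - |b*|/||b*||_1 ||_1` computed on
#' component magnitudes of the L1-normalized vectors (signs are not
#' identifiable in the bilinear model). Undefined denominators yield `NA`.
#'
#' @param beta_hat estimated (thresholded) coefficient vector.
#' @param beta_star true coefficient vector, same length.
#' @return List with `tpr`, `fpr`, `l1_bias`.
#' @export
selection_metrics <- function(beta_hat, beta_star) {
  if (length(beta_hat) != length(beta_star)) stop_clusso("coefficient lengths differ")
  nz <- beta_star != 0
  tpr <- if (any(nz)) mean(beta_hat[nz] != 0) else NA_real_
  fpr <- if (any(!nz)) mean(beta_hat[!nz] != 0) else NA_real_
  norm1 <- function(v) if (sum(abs(v)) > 0) abs(v) / sum(abs(v)) else abs(v)
  l1_bias <- sum(abs(norm1(beta_hat) - norm1(beta_star)))
  list(tpr = tpr, fpr = fpr, l1_bias = l1_bias)
}

#' Run the simulation harness over a grid of settings
#'
#' For every setting and repetition, generates a dataset, fits the requested
#' methods, and computes TPR/FPR/L1 bias of the thresholded normalized beta,
#' in-sample prediction MSE, the dropped-subject fraction, and (for CLUSSO
#' with a correctly specified number of subgroups) the clustering accuracy.
#' Summaries follow the study's aggregation: medians across repetitions for
#' all metrics except clustering accuracy, which is the mean across
#' repetitions of per-repetition subject means. Per-repetition seeds are
#' derived deterministically from `seed`; one truth (per q, s_beta and
#' subgroup count) is shared across settings and repetitions. Failed
#' repetitions are counted and excluded, never silently dropped.
#'
#' @param settings data.frame with columns `n`, `q`, `s_beta`, `scenario`,
#'   `sigma2_R` (and optionally `sigma2_eps`, `mu_M`, `sigma2_M`, `G_fit`).
#' @param methods subset of `c("clusso", "naive", "full_info")`.
#' @param reps repetitions per setting.
#' @param seed master seed.
#' @param cluster_algorithm clustering algorithm for CLUSSO.
#' @param lambda_grid structured-lasso CV grid.
#' @param n_folds,n_inits,threshold passed to [clusso()].
#' @param cache_dir optional directory; per-repetition results are written as
#'   CSV and reused on rerun, making long grids resumable.
#' @param verbose print progress?
#' @return List with `summary` (one row per setting x method) and `per_rep`
#'   (one row per setting x rep x method).
#' @export
run_simulation <- function(settings, methods = c("clusso", "naive", "full_info"),
                           reps = 10L, seed = 1L, cluster_algorithm = "gmm",
                           lambda_grid = seq(0.5, 5, by = 0.5), n_folds = 5L,
                           n_inits = 5L, threshold = 0.001, cache_dir = NULL,
                           verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  settings <- as.data.frame(settings)
  if (!nrow(settings)) stop_clusso("empty settings grid")
  defaults <- list(sigma2_eps = 1, mu_M = 40, sigma2_M = 5)
  for (nm in names(defaults)) if (is.null(settings[[nm]])) settings[[nm]] <- defaults[[nm]]
  if (is.null(settings$G_fit)) settings$G_fit <- 2L
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)

  per_rep <- list()
  for (s in seq_len(nrow(settings))) {
    cfg <- settings[s, ]
    G_true <- scenario_G(cfg$scenario)
    truth <- generate_truth(cfg$q, cfg$s_beta, G_true, seed = derive_seed(seed, 424242L, cfg$q, round(100 * cfg$s_beta), G_true))
    for (r in seq_len(reps)) {
      tag <- sprintf("s%03d_r%04d", s, r)
      cache_file <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(tag, ".csv")) else NULL
      if (!is.null(cache_file) && file.exists(cache_file)) {
        per_rep[[tag]] <- read.csv(cache_file, stringsAsFactors = FALSE)
        next
      }
      res <- simulate_one_rep(cfg, truth, methods, seed_rep = derive_seed(seed, s, r),
                              cluster_algorithm, lambda_grid, n_folds, n_inits, threshold)
      res$setting <- s; res$rep <- r
      if (!is.null(cache_file)) write.csv(res, cache_file, row.names = FALSE)
      per_rep[[tag]] <- res
      if (verbose) message(sprintf("setting %d rep %d done", s, r))
    }
  }
  per_rep <- do.call(rbind, per_rep)
  rownames(per_rep) <- NULL

  ok <- per_rep[!per_rep$failed, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(ok, list(ok$setting, ok$method), drop = TRUE), function(d) {
    data.frame(setting = d$setting[1], method = d$method[1],
               tpr = median(d$tpr, na.rm = TRUE), fpr = median(d$fpr, na.rm = TRUE),
               l1_bias = median(d$l1_bias, na.rm = TRUE), mse = median(d$mse, na.rm = TRUE),
               clustering_accuracy = mean(d$clustering_accuracy, na.rm = TRUE),
               dropped_frac = mean(d$dropped_frac, na.rm = TRUE),
               n_reps = nrow(d),
               n_failed = sum(per_rep$failed[per_rep$setting == d$setting[1] &
                                               per_rep$method == d$method[1]]),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$setting, summ$method), ]
  rownames(summ) <- NULL
  list(summary = cbind(settings[summ$setting, c("n", "q", "s_beta", "scenario", "sigma2_R")],
                       summ[, -1, drop = FALSE]),
       per_rep = per_rep)
}

simulate_one_rep <- function(cfg, truth, methods, seed_rep, cluster_algorithm,
                             lambda_grid, n_folds, n_inits, threshold) {
  dat <- generate_dataset(cfg$n, cfg$q, truth, scenario = cfg$scenario,
                          sigma2_eps = cfg$sigma2_eps, sigma2_R = cfg$sigma2_R,
                          mu_M = cfg$mu_M, sigma2_M = cfg$sigma2_M, seed = seed_rep)
  out <- lapply(methods, function(m) {
    row <- data.frame(method = m, tpr = NA_real_, fpr = NA_real_, l1_bias = NA_real_,
                      mse = NA_real_, clustering_accuracy = NA_real_,
                      dropped_frac = NA_real_, lambda = NA_real_, failed = FALSE,
                      error = "", stringsAsFactors = FALSE)
    fit <- tryCatch(
      switch(m,
        clusso = suppressWarnings(
          clusso(dat$tubules, dat$outcomes, method = "clusso", G = cfg$G_fit,
                 cluster_algorithm = cluster_algorithm, lambda_grid = lambda_grid,
                 n_folds = n_folds, n_inits = n_inits, threshold = threshold,
                 seed = seed_rep)),
        full_info = clusso(outcomes = dat$outcomes, method = "full_info",
                           truth = dat$truth, lambda_grid = lambda_grid,
                           n_folds = n_folds, n_inits = n_inits,
                           threshold = threshold, seed = seed_rep),
        naive = clusso(dat$tubules, dat$outcomes, method = "naive",
                       n_folds = n_folds, threshold = threshold, seed = seed_rep)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      row$failed <- TRUE; row$error <- conditionMessage(fit)
      return(row)
    }
    met <- selection_metrics(fit$beta_norm, truth$beta_star)
    row$tpr <- met$tpr; row$fpr <- met$fpr; row$l1_bias <- met$l1_bias
    row$mse <- fit$mse; row$lambda <- fit$lambda
    n_total <- length(fit$subjects) + length(fit$dropped)
    row$dropped_frac <- length(fit$dropped) / n_total
    if (m == "clusso" && cfg$G_fit == scenario_G(cfg$scenario)) {
      row$clustering_accuracy <- clustering_accuracy(
        fit$clustering$labels, dat$true_labels, dat$tubules$subject_id, G = cfg$G_fit)
    }
    row
  })
  do.call(rbind, out)
}
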