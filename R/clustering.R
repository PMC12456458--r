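## Unsupervised clustering of the pooled object table into G latent subgroups,
## classification of new objects with a trained model, and the
## best-permutation clustering accuracy score.

#' Cluster all pooled objects into G latent subgroups
#'
#' Pools every object row across subjects and fits either a G-component
#' Gaussian mixture (full covariances, EM) or k-means. Features are
#' column-standardized over the pooled table by default so the clustering is
#' scale-invariant. The fit is deterministic given `seed`.
#'
#' @param tubules a [tubule_table()].
#' @param G number of latent subgroups (>= 1).
#' @param algorithm `"gmm"` (Gaussian mixture via EM) or `"kmeans"`.
#' @param seed integer seed controlling initialization.
#' @param standardize_features standardize pooled feature columns first?
#' @return An object of class `clusso_clustering` with elements `labels`
#'   (integer vector aligned to the rows of `tubules`), `G`, `algorithm`,
#'   `params` (fitted mixture/centroid parameters on the standardized scale),
#'   `center`/`scale` (the feature standardization), `loglik` (gmm only) and
#'   `seed`.
#' @export
cluster_pooled <- function(tubules, G, algorithm = c("gmm", "kmeans"), seed = 1L,
                           standardize_features = TRUE) {
  algorithm <- match.arg(algorithm)
  X <- feature_matrix(tubules)
  N <- nrow(X)
  if (G < 1L) stop_clusso("G must be >= 1")
  if (G > N) stop_clusso("G = %d exceeds the pooled object count %d", G, N)
  if (standardize_features) {
    ctr <- unname(colMeans(X))
    scl <- unname(apply(X, 2, sd))
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  dimnames(Z) <- NULL

  if (G == 1L) {
    params <- list(pro = 1, mean = matrix(colMeans(Z), ncol = 1),
                   sigma = list(unname(stats::cov(Z) * (N - 1) / N)))
    fit <- list(labels = rep(1L, N), params = params, loglik = NA_real_)
  } else if (algorithm == "gmm") {
    fit <- fit_gmm_pooled(Z, G, seed)
  } else {
    fit <- fit_kmeans_pooled(Z, G, seed)
  }
  structure(list(labels = fit$labels, G = as.integer(G), algorithm = algorithm,
                 params = fit$params, center = ctr, scale = scl,
                 feature_names = feature_names(tubules),
                 loglik = fit$loglik, seed = as.integer(seed)),
            class = "clusso_clustering")
}

## GMM with unconstrained ("VVV") component covariances: seeded k-means
## initialization, EM (mclust) run on a seeded subsample of at most
## `em_max_points` rows when the pooled table is very large (mixture
## parameters stabilize long before that), then a single E-step over all
## rows for the posterior labels. Deterministic given the seed.
fit_gmm_pooled <- function(Z, G, seed, em_max_points = 25000L) {
  N <- nrow(Z)
  model_name <- if (ncol(Z) == 1L) "V" else "VVV"
  fit <- withr::with_seed(seed, {
    idx <- if (N > em_max_points) sample.int(N, em_max_points) else seq_len(N)
    dat <- if (model_name == "V") Z[idx, 1] else Z[idx, , drop = FALSE]
    km <- kmeans(Z[idx, , drop = FALSE], centers = G, nstart = 3L, iter.max = 100L)
    mclust::me(modelName = model_name, data = dat,
               z = mclust::unmap(km$cluster, groups = seq_len(G)))
  })
  if (is.null(fit) || is.na(fit$loglik)) {
    stop_clusso("EM for the %d-component Gaussian mixture failed to converge", G)
  }
  p <- fit$parameters
  sig <- lapply(seq_len(G), function(k) {
    s <- p$variance$sigma
    s <- if (length(dim(s)) == 3) s[, , k] else matrix(p$variance$sigmasq[k], 1, 1)
    unname(as.matrix(s))
  })
  params <- list(pro = as.numeric(p$pro),
                 mean = unname(matrix(p$mean, ncol = G)),
                 sigma = sig)
  post <- gmm_posterior(params, Z)
  list(labels = max.col(post, ties.method = "first"), params = params,
       loglik = fit$loglik)
}

fit_kmeans_pooled <- function(Z, G, seed) {
  km <- withr::with_seed(seed, kmeans(Z, centers = G, nstart = 5L, iter.max = 100L))
  ## re-assign with the documented tie-break (lowest cluster index wins)
  labels <- nearest_centroid(Z, km$centers)
  list(labels = labels, params = list(centers = unname(km$centers)), loglik = NA_real_)
}

## nearest-centroid labels; exact ties go to the lowest cluster index
nearest_centroid <- function(Z, centers) {
  d2 <- outer(rowSums(Z^2), rep(1, nrow(centers))) -
    2 * Z %*% t(centers) + outer(rep(1, nrow(Z)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

## log multivariate normal density, full covariance
log_dmvnorm <- function(Z, mu, Sigma) {
  q <- length(mu)
  ch <- chol(Sigma)
  w <- backsolve(ch, t(Z) - mu, transpose = TRUE)
  -0.5 * colSums(w^2) - sum(log(diag(ch))) - 0.5 * q * log(2 * pi)
}

## posterior responsibilities of a fitted gmm on (already standardized) rows
gmm_posterior <- function(params, Z) {
  G <- length(params$pro)
  ll <- vapply(seq_len(G), function(k) {
    log(params$pro[k]) + log_dmvnorm(Z, params$mean[, k], params$sigma[[k]])
  }, numeric(nrow(Z)))
  ll <- matrix(ll, nrow = nrow(Z))
  m <- apply(ll, 1, max)
  p <- exp(ll - m)
  p / rowSums(p)
}

#' Classify new objects with a trained cluster model
#'
#' Applies the stored feature standardization, then labels each object by
#' maximum posterior responsibility (gmm) or nearest centroid (k-means).
#' No refitting takes place.
#'
#' @param model a `clusso_clustering` object from [cluster_pooled()].
#' @param tubules a [tubule_table()] with the same feature count as training.
#' @return A `clusso_clustering` object for the new table (same `params`).
#' @export
assign_new <- function(model, tubules) {
  X <- feature_matrix(tubules)
  if (ncol(X) != length(model$center)) {
    stop_clusso("feature count mismatch: model has q = %d, new data has q = %d",
                length(model$center), ncol(X))
  }
  Z <- sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
  labels <- if (model$G == 1L) {
    rep(1L, nrow(Z))
  } else if (model$algorithm == "gmm") {
    max.col(gmm_posterior(model$params, Z), ties.method = "first")
  } else {
    nearest_centroid(Z, model$params$centers)
  }
  out <- model
  out$labels <- as.integer(labels)
  out
}

#' Best-permutation clustering accuracy, averaged across subjects
#'
#' Chooses the single global permutation of the estimated labels (over all G!
#' permutations) that maximizes overall agreement with the true labels, then
#' computes the per-subject proportion of agreeing objects and returns the
#' mean across subjects. Invariant to relabeling of either argument.
#'
#' @param estimated integer labels in 1..G (or a `clusso_clustering` object).
#' @param truth integer true labels in 1..G, same length.
#' @param subject_ids subject identifier per object, same length.
#' @param G number of subgroups; defaults to the maximum label seen.
#' @return Mean per-subject agreement in \[0, 1\].
#' @export
clustering_accuracy <- function(estimated, truth, subject_ids, G = NULL) {
  if (inherits(estimated, "clusso_clustering")) {
    G <- G %||% estimated$G
    estimated <- estimated$labels
  }
  G <- G %||% max(estimated, truth)
  if (length(estimated) != length(truth) || length(truth) != length(subject_ids)) {
    stop_clusso("estimated, truth and subject_ids must have equal lengths")
  }
  if (any(estimated < 1L | estimated > G) || any(truth < 1L | truth > G)) {
    stop_clusso("labels must lie in 1..G")
  }
  perms <- permutations(G)
  conf <- table(factor(estimated, levels = seq_len(G)), factor(truth, levels = seq_len(G)))
  agree <- vapply(seq_len(nrow(perms)), function(r) {
    sum(conf[cbind(seq_len(G), perms[r, ])])
  }, numeric(1))
  best <- perms[which.max(agree), ]
  mapped <- best[estimated]
  per_subject <- tapply(mapped == truth, subject_ids, mean)
  mean(per_subject)
}

#' @export
print.clusso_clustering <- function(x, ...) {
  cat(sprintf("Object clustering: %s, G = %d, %d objects\n",
              x$algorithm, x$G, length(x$labels)))
  tab <- table(x$labels)
  cat("Cluster sizes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
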