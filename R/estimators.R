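## End-to-end fitting of the three strategies (CLUSSO, Full Information
## oracle, naive averaging lasso) and prediction with train/test cluster
## correspondence resolution.

#' Fit a scalar-on-matrix regression to ragged object-level features
#'
#' The main fitting entry point. Three strategies share one interface:
#' \describe{
#'   \item{`"clusso"`}{pool all objects, cluster them into `G` latent
#'     subgroups, average features within subject x cluster, weight rows by
#'     the observed cluster proportions, standardize, and fit the constrained
#'     bilinear lasso with lambda chosen by cross-validation.}
#'   \item{`"full_info"`}{the oracle: identical, but built from the true
#'     latent cluster-mean matrices and true proportions supplied in `truth`
#'     (simulation use only).}
#'   \item{`"naive"`}{average every feature over all of a subject's objects
#'     and fit an ordinary lasso on the subject-level means, with a 100-value
#'     log-spaced lambda path from `lambda_max` (the smallest lambda with an
#'     all-zero solution) down to `lambda_max * 1e-4`.}
#' }
#' In all cases the final column-effect vector is L1-normalized and
#' components below `threshold` are zeroed for reporting/selection; the
#' un-normalized solution is kept for prediction.
#'
#' @param tubules a [tubule_table()] (ignored for `method = "full_info"`).
#' @param outcomes an [outcome_vector()] data.frame (`subject_id`, `y`).
#' @param method one of `"clusso"`, `"naive"`, `"full_info"`.
#' @param truth a `clusso_truth` object (required for `"full_info"`).
#' @param G number of latent subgroups (default 2).
#' @param cluster_algorithm `"gmm"` or `"kmeans"`.
#' @param lambda_grid candidate lambdas for the structured lasso CV
#'   (default `seq(0.5, 5, by = 0.5)`); ignored for `"naive"`, which builds
#'   its own path.
#' @param n_folds CV folds (default 5).
#' @param n_inits random initializations per structured-lasso solve (default 5).
#' @param threshold magnitude threshold applied to the L1-normalized beta.
#' @param seed integer seed governing clustering initialization, CV folds and
#'   random starts; fixing it makes the whole fit reproducible.
#' @param standardize_features standardize pooled features before clustering?
#' @param tol,max_iter convergence control for the alternating solver.
#' @return An object of class `clusso` with (among others) elements `alpha`,
#'   `beta` (un-normalized), `beta_norm` (L1-normalized, thresholded),
#'   `lambda`, `cv_table`, `transform`, `clustering`, `subjects`, `dropped`,
#'   `fitted`, `mse`.
#' @export
clusso <- function(tubules, outcomes, method = c("clusso", "naive", "full_info"),
                   truth = NULL, G = 2L, cluster_algorithm = c("gmm", "kmeans"),
                   lambda_grid = seq(0.5, 5, by = 0.5), n_folds = 5L, n_inits = 5L,
                   threshold = 0.001, seed = 1L,
                   standardize_features = TRUE, tol = 1e-6, max_iter = 200L) {
  method <- match.arg(method)
  cluster_algorithm <- match.arg(cluster_algorithm)
  if (is.unsorted(lambda_grid)) stop_clusso("lambda_grid must be ascending")
  if (threshold < 0) stop_clusso("threshold must be >= 0")

  if (method == "naive") {
    return(fit_naive(tubules, outcomes, n_folds = n_folds, threshold = threshold,
                     seed = seed))
  }

  if (method == "full_info") {
    if (is.null(truth)) stop_clusso("method 'full_info' requires the simulation truth")
    design <- build_full_info_design(truth)
    clustering <- NULL
    outcomes <- outcome_vector(outcomes)
  } else {
    paired <- pair_dataset(tubules, outcome_vector(outcomes))
    tubules <- paired$tubules; outcomes <- paired$outcomes
    clustering <- cluster_pooled(tubules, G, cluster_algorithm, seed,
                                 standardize_features)
    design <- build_design(tubules, clustering, G)
    if (length(design$dropped) > 0.5 * (length(design$subjects) + length(design$dropped))) {
      warn_clusso(paste("more than half of the subjects lack an object in every cluster;",
                        "the objects may come from a single latent subgroup, in which",
                        "case the naive averaging method may be sufficient"))
    }
  }

  y <- outcomes$y[match(design$subjects, outcomes$subject_id)]
  if (anyNA(y)) stop_clusso("outcomes missing for some designed subjects")
  std <- standardize_design(design, y)
  cv <- cv_lambda(std$X, std$y, lambda_grid, n_folds, seed = seed, n_inits = n_inits,
                  tol = tol, max_iter = max_iter)
  sol <- solve_multi_init(std$X, std$y, cv$lambda, n_inits,
                          seed = derive_seed(seed, 777L), tol = tol, max_iter = max_iter)
  beta_norm <- normalize_threshold(sol$beta, threshold)
  fitted_y <- predict_bilinear(sol$alpha, sol$beta, std$X) + std$transform$y_mean

  structure(list(
    method = method, G = design$G, q = design$q,
    feature_names = design$feature_names,
    alpha = as.numeric(sol$alpha), beta = as.numeric(sol$beta),
    beta_norm = beta_norm, lambda = cv$lambda, threshold = threshold,
    objective = sol$objective, converged = sol$converged, n_iter = sol$n_iter,
    cv_table = cv$cv_table,
    transform = unclass(std$transform),
    clustering = if (is.null(clustering)) NULL else unclass(clustering),
    subjects = design$subjects, dropped = design$dropped,
    fitted = fitted_y, y = y, mse = mean((y - fitted_y)^2),
    n = length(y), n_folds = as.integer(n_folds), n_inits = as.integer(n_inits),
    seed = as.integer(seed)), class = "clusso")
}

## naive averaging lasso: subject-level feature means, glmnet path per the
## Friedman et al. convention (rescaled to the (1/n) RSS objective)
fit_naive <- function(tubules, outcomes, n_folds = 5L, threshold = 0.001, seed = 1L) {
  paired <- pair_dataset(tubules, outcome_vector(outcomes))
  tubules <- paired$tubules; outcomes <- paired$outcomes
  X <- feature_matrix(tubules)
  xbar <- rowsum(X, tubules$subject_id) / as.vector(table(tubules$subject_id))
  subjects <- rownames(xbar)
  y <- outcomes$y[match(subjects, outcomes$subject_id)]
  n <- length(y); q <- ncol(xbar)

  col_mean <- colMeans(xbar)
  col_sd <- apply(xbar, 2, sd)
  if (any(col_sd == 0)) {
    stop_clusso("zero-variance feature column '%s' in the subject means",
                feature_names(tubules)[which(col_sd == 0)[1]])
  }
  Xs <- sweep(sweep(xbar, 2, col_mean, "-"), 2, col_sd, "/")
  y_mean <- mean(y); yc <- y - y_mean

  grid <- naive_lambda_grid(Xs, yc)
  foldid <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  if (q >= 2L) {
    ## glmnet minimizes (1/2n)RSS + lambda ||b||_1: halve our (1/n)-scale grid
    cvfit <- glmnet::cv.glmnet(Xs, yc, lambda = grid / 2, foldid = foldid,
                               standardize = FALSE, intercept = FALSE)
    sel <- cvfit$lambda.min * 2
    beta <- as.numeric(coef(cvfit, s = cvfit$lambda.min))[-1]
    cv_table <- data.frame(lambda = cvfit$lambda * 2, mse_mean = cvfit$cvm,
                           mse_sd = cvfit$cvsd)
  } else {
    ## single feature: closed-form soft-threshold path, manual CV
    lasso1 <- function(x, y, lam) {
      a <- 2 * sum(x^2) / length(y)
      cc <- 2 * sum(x * y) / length(y)
      soft <- sign(cc) * max(abs(cc) - lam, 0)
      soft / a
    }
    mse <- sapply(grid, function(lam) {
      mean(sapply(seq_len(n_folds), function(f) {
        b <- lasso1(Xs[foldid != f, 1], yc[foldid != f], lam)
        mean((yc[foldid == f] - Xs[foldid == f, 1] * b)^2)
      }))
    })
    sel <- grid[which.min(mse)]
    beta <- lasso1(Xs[, 1], yc, sel)
    cv_table <- data.frame(lambda = grid, mse_mean = mse, mse_sd = NA_real_)
  }
  beta_norm <- normalize_threshold(beta, threshold)
  fitted_y <- as.numeric(Xs %*% beta) + y_mean

  structure(list(
    method = "naive", G = NULL, q = q, feature_names = feature_names(tubules),
    alpha = NULL, beta = beta, beta_norm = beta_norm,
    lambda = sel, lambda_max = max(grid), threshold = threshold,
    objective = mean((yc - as.numeric(Xs %*% beta))^2) + sel * sum(abs(beta)),
    converged = TRUE, n_iter = NA_integer_,
    cv_table = cv_table,
    transform = list(col_mean = col_mean, col_sd = col_sd, y_mean = y_mean),
    clustering = NULL, subjects = subjects, dropped = character(0),
    fitted = fitted_y, y = y, mse = mean((y - fitted_y)^2),
    n = n, n_folds = as.integer(n_folds), n_inits = NA_integer_,
    seed = as.integer(seed)), class = "clusso")
}

#' Friedman-style lambda path for the naive lasso
#'
#' 100 log-spaced values from `lambda_max` (the smallest lambda at which all
#' coefficients of the `(1/n) RSS + lambda ||b||_1` lasso are zero, i.e.
#' `(2/n) max_j |<x_j, y>|`) down to `lambda_max * 1e-4`.
#'
#' @param Xs standardized subject-level design matrix.
#' @param yc centered outcomes.
#' @return Decreasing numeric vector of length 100.
#' @export
naive_lambda_grid <- function(Xs, yc) {
  lambda_max <- max(abs(crossprod(Xs, yc))) * 2 / length(yc)
  exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100))
}

#' Predict outcomes for new subjects, resolving cluster correspondence
#'
#' For a CLUSSO fit, the test objects are labeled with the trained cluster
#' model (or independently re-clustered with `recluster = TRUE`), the
#' cluster-averaged weighted design is built and standardized with the
#' training transform, and predictions are computed under every permutation
#' of the cluster-row order, since the labeling of clusters in new data need
#' not correspond to the training labels. If test outcomes are supplied, the
#' per-permutation MSE is reported and the minimizing correspondence flagged.
#' Naive fits predict directly from the subject-level feature means.
#'
#' @param object a fitted `clusso` model.
#' @param tubules a [tubule_table()] of test objects (features must match
#'   training).
#' @param outcomes optional test [outcome_vector()] data.frame.
#' @param truth optional `clusso_truth` for the test subjects (required to
#'   predict from a `full_info` fit).
#' @param recluster cluster the test objects from scratch instead of applying
#'   the trained model?
#' @param seed seed for `recluster = TRUE`.
#' @param ... unused.
#' @return A `clusso_prediction`: `subjects`, `permutations` (G! x G matrix),
#'   `predictions` (subjects x permutations), `mse` (per permutation, if
#'   outcomes were given), `chosen` (index of the MSE-minimizing
#'   permutation), and `dropped`.
#' @export
predict.clusso <- function(object, tubules = NULL, outcomes = NULL, truth = NULL,
                           recluster = FALSE, seed = 1L, ...) {
  if (object$method == "naive") {
    if (is.null(tubules)) stop_clusso("naive prediction requires a tubule table")
    check_features(object, tubules)
    X <- feature_matrix(tubules)
    xbar <- rowsum(X, tubules$subject_id) / as.vector(table(tubules$subject_id))
    Xs <- sweep(sweep(xbar, 2, object$transform$col_mean, "-"), 2,
                object$transform$col_sd, "/")
    pred <- matrix(as.numeric(Xs %*% object$beta) + object$transform$y_mean, ncol = 1)
    return(finish_prediction(object, rownames(xbar), matrix(1L, 1, 1), pred,
                             outcomes, character(0)))
  }

  if (object$method == "full_info") {
    if (is.null(truth)) stop_clusso("predicting from a full_info fit requires the truth")
    design <- build_full_info_design(truth)
  } else {
    if (is.null(tubules)) stop_clusso("prediction requires a tubule table")
    check_features(object, tubules)
    labels <- if (recluster) {
      cluster_pooled(tubules, object$G, object$clustering$algorithm, seed,
                     standardize_features = !all(object$clustering$scale == 1))
    } else {
      assign_new(object$clustering, tubules)
    }
    design <- build_design(tubules, labels, object$G)
  }

  perms <- permutations(object$G)
  tf <- object$transform
  n <- length(design$subjects)
  pred <- matrix(NA_real_, n, nrow(perms))
  for (r in seq_len(nrow(perms))) {
    A <- design$X_dstar[perms[r, ], , , drop = FALSE]
    for (i in seq_len(n)) {
      Zi <- (A[, , i] - tf$cell_mean) / tf$cell_sd
      pred[i, r] <- sum(object$alpha * (Zi %*% object$beta)) + tf$y_mean
    }
  }
  finish_prediction(object, design$subjects, perms, pred, outcomes, design$dropped)
}

check_features <- function(object, tubules) {
  if (!identical(unname(feature_names(tubules)), unname(object$feature_names))) {
    stop_clusso("test feature columns do not match the training features")
  }
}

finish_prediction <- function(object, subjects, perms, pred, outcomes, dropped) {
  mse <- chosen <- NULL
  if (!is.null(outcomes)) {
    outcomes <- outcome_vector(outcomes)
    y <- outcomes$y[match(subjects, outcomes$subject_id)]
    if (anyNA(y)) stop_clusso("test outcomes missing for some subjects")
    mse <- colMeans((pred - y)^2)
    chosen <- which.min(mse)
  }
  structure(list(subjects = subjects, permutations = perms, predictions = pred,
                 mse = mse, chosen = chosen, dropped = dropped,
                 method = object$method),
            class = "clusso_prediction")
}

## ---- standard modelling methods ----------------------------------------

#' @export
print.clusso <- function(x, ...) {
  lab <- c(clusso = "CLUSSO (clustering structured lasso)",
           full_info = "Full Information structured lasso (oracle)",
           naive = "Naive averaging lasso")[x$method]
  cat(lab, "\n")
  cat(sprintf("  n = %d subjects (%d dropped), q = %d features%s\n", x$n,
              length(x$dropped), x$q,
              if (!is.null(x$G)) sprintf(", G = %d clusters", x$G) else ""))
  cat(sprintf("  lambda = %g (%d-fold CV), in-sample MSE = %.4g\n",
              x$lambda, x$n_folds, x$mse))
  nz <- sum(x$beta_norm != 0)
  cat(sprintf("  selected features (|beta| >= %g after L1 normalization): %d of %d\n",
              x$threshold, nz, x$q))
  invisible(x)
}

#' @export
summary.clusso <- function(object, ...) {
  sel <- which(object$beta_norm != 0)
  out <- list(model = object,
              selected = data.frame(feature = object$feature_names[sel],
                                    beta_normalized = object$beta_norm[sel],
                                    magnitude = abs(object$beta_norm[sel])))
  class(out) <- "summary.clusso"
  out
}

#' @export
print.summary.clusso <- function(x, ...) {
  print(x$model)
  if (!is.null(x$model$alpha)) {
    cat("  cluster (row) effects alpha:", paste(signif(x$model$alpha, 4), collapse = " "), "\n")
  }
  if (nrow(x$selected)) {
    cat("\nSelected features (L1-normalized coefficients):\n")
    print(x$selected, row.names = FALSE)
  } else {
    cat("\nNo features selected.\n")
  }
  invisible(x)
}

#' Extract column-effect coefficients
#' @param object a fitted `clusso` model.
#' @param normalized return the L1-normalized, thresholded vector (default)
#'   or the raw solution?
#' @param ... unused.
#' @export
coef.clusso <- function(object, normalized = TRUE, ...) {
  b <- if (normalized) object$beta_norm else object$beta
  names(b) <- object$feature_names
  b
}

#' @export
fitted.clusso <- function(object, ...) {
  structure(object$fitted, names = object$subjects)
}

#' @export
residuals.clusso <- function(object, ...) {
  structure(object$y - object$fitted, names = object$subjects)
}

#' Plot the cross-validation curve of a fit
#' @param x a fitted `clusso` model.
#' @param ... passed to [plot()].
#' @export
plot.clusso <- function(x, ...) {
  tab <- x$cv_table
  graphics::plot(tab$lambda, tab$mse_mean, type = "b", log = if (x$method == "naive") "x" else "",
                 xlab = expression(lambda), ylab = "CV mean squared error", ...)
  graphics::abline(v = x$lambda, lty = 2)
  invisible(x)
}

#' @export
print.clusso_prediction <- function(x, ...) {
  cat(sprintf("Predictions for %d subjects (%d correspondence permutation(s))\n",
              length(x$subjects), nrow(x$permutations)))
  if (!is.null(x$mse)) {
    cat("Test MSE per correspondence:", paste(signif(x$mse, 5), collapse = ", "), "\n")
    cat(sprintf("Chosen correspondence: %d (%s)\n", x$chosen,
                paste(x$permutations[x$chosen, ], collapse = " ")))
  }
  if (length(x$dropped)) cat("Dropped test subjects:", length(x$dropped), "\n")
  invisible(x)
}
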