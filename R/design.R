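## Per-subject cluster-averaged, proportion-weighted G x q design matrices and
## the per-cell standardization applied before the structured lasso.

#' Build per-subject cluster-averaged and weighted design matrices
#'
#' For each subject i, row k of `X_star` is the mean feature vector over the
#' subject's objects labeled k, `w[k]` is the observed proportion of the
#' subject's objects in cluster k, and `X_dstar = diag(w) %*% X_star`.
#' Subjects lacking at least one object in every cluster have an undefined
#' cluster average and are dropped (and reported).
#'
#' @param tubules a [tubule_table()].
#' @param labels integer labels aligned to the rows of `tubules`, or a
#'   `clusso_clustering` object from [cluster_pooled()].
#' @param G number of clusters.
#' @return A `clusso_design` object: `subjects` (retained ids, sorted),
#'   `G`, `q`, `X_star` and `X_dstar` (G x q x n arrays), `w` (n x G matrix),
#'   `feature_names`, and `dropped` (character vector of excluded subjects).
#' @export
build_design <- function(tubules, labels, G) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  X <- feature_matrix(tubules)
  if (length(labels) != nrow(X)) stop_clusso("labels not aligned to tubule table rows")
  if (any(labels < 1L | labels > G)) stop_clusso("labels must lie in 1..G")
  sid <- tubules$subject_id
  subjects <- sort(unique(sid))
  n_all <- length(subjects)
  g <- (match(sid, subjects) - 1L) * G + labels        # group code in 1..(n_all*G)
  counts <- matrix(tabulate(g, nbins = n_all * G), nrow = G)           # G x n
  sums <- rowsum(X, g)                                 # only groups actually seen
  ## expand sums to the full (n*G) x q grid
  full <- matrix(0, n_all * G, ncol(X))
  full[as.integer(rownames(sums)), ] <- sums
  keep <- colSums(counts == 0) == 0
  if (!any(keep)) {
    stop_clusso(paste("every subject lacks an object in some cluster; the cluster-averaged",
                      "design is undefined -- consider the naive averaging method instead"))
  }
  q <- ncol(X)
  n <- sum(keep)
  X_star <- array(0, c(G, q, n))
  w <- matrix(0, n, G)
  idx <- which(keep)
  for (j in seq_len(n)) {
    i <- idx[j]
    rows <- (i - 1L) * G + seq_len(G)
    ci <- counts[, i]
    X_star[, , j] <- full[rows, , drop = FALSE] / ci
    w[j, ] <- ci / sum(ci)
  }
  X_dstar <- sweep_rows(X_star, w)
  structure(list(subjects = subjects[keep], G = as.integer(G), q = q,
                 X_star = X_star, w = w, X_dstar = X_dstar,
                 feature_names = feature_names(tubules),
                 dropped = subjects[!keep]),
            class = "clusso_design")
}

## multiply row k of each G x q slice by w[i, k]
sweep_rows <- function(A, w) {
  out <- A
  for (j in seq_len(dim(A)[3])) out[, , j] <- A[, , j] * w[j, ]
  out
}

#' Build the Full Information (oracle) design from simulation truth
#'
#' Uses the true latent cluster-mean matrices X* and true proportions w, so
#' `X_dstar = diag(w) %*% X_star` exactly and no subjects are dropped.
#'
#' @param truth a `clusso_truth` object from [generate_dataset()] (fields
#'   `X_star`: G x q x n array, `w`: n x G matrix, `subjects`).
#' @return A `clusso_design` object.
#' @export
build_full_info_design <- function(truth) {
  w <- truth$w
  if (any(w <= 0 | w >= 1) && ncol(w) > 1L) {
    stop_clusso("true cluster proportions must lie strictly in (0, 1)")
  }
  G <- dim(truth$X_star)[1]; q <- dim(truth$X_star)[2]
  structure(list(subjects = truth$subjects, G = as.integer(G), q = q,
                 X_star = truth$X_star, w = w,
                 X_dstar = sweep_rows(truth$X_star, w),
                 feature_names = truth$feature_names %||% paste0("f", seq_len(q)),
                 dropped = character(0)),
            class = "clusso_design")
}

#' Standardize a design and center outcomes
#'
#' Z-scores each of the G*q design cells across subjects (so every entry of
#' the weighted design has mean 0 and unit variance over the sample, matching
#' the distributional assumption on the design) and centers y. The transform
#' is stored so it can be applied unchanged to test-set designs.
#'
#' @param design a `clusso_design`.
#' @param y numeric outcomes aligned to `design$subjects`.
#' @return List with `X` (standardized G x q x n array), `y` (centered),
#'   and `transform` (a `clusso_standardization`: `cell_mean`, `cell_sd`
#'   G x q matrices and `y_mean`).
#' @export
standardize_design <- function(design, y) {
  n <- dim(design$X_dstar)[3]
  if (length(y) != n) stop_clusso("outcome length %d does not match %d retained subjects", length(y), n)
  if (n < 2L) stop_clusso("need at least 2 retained subjects to standardize")
  A <- design$X_dstar
  cell_mean <- apply(A, c(1, 2), mean)
  cell_sd <- apply(A, c(1, 2), sd)
  zv <- which(cell_sd == 0, arr.ind = TRUE)
  if (nrow(zv)) {
    stop_clusso("zero-variance design cell (cluster %d, feature %d)", zv[1, 1], zv[1, 2])
  }
  transform <- structure(list(cell_mean = cell_mean, cell_sd = cell_sd, y_mean = mean(y)),
                         class = "clusso_standardization")
  list(X = apply_standardization(transform, A), y = y - transform$y_mean,
       transform = transform)
}

#' Apply a stored standardization transform to a design array
#' @param transform a `clusso_standardization`.
#' @param A a G x q x n design array (or a `clusso_design`, whose `X_dstar` is used).
#' @return Standardized G x q x n array.
#' @export
apply_standardization <- function(transform, A) {
  if (inherits(A, "clusso_design")) A <- A$X_dstar
  out <- A
  for (j in seq_len(dim(A)[3])) {
    out[, , j] <- (A[, , j] - transform$cell_mean) / transform$cell_sd
  }
  out
}

#' Invert a standardization transform
#' @inheritParams apply_standardization
#' @return The design array on the original scale.
#' @export
invert_standardization <- function(transform, A) {
  out <- A
  for (j in seq_len(dim(A)[3])) {
    out[, , j] <- A[, , j] * transform$cell_sd + transform$cell_mean
  }
  out
}

#' @export
print.clusso_design <- function(x, ...) {
  cat(sprintf("Cluster-averaged design: %d subjects, G = %d, q = %d (%d dropped)\n",
              length(x$subjects), x$G, x$q, length(x$dropped)))
  invisible(x)
}
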