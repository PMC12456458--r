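test_that("CLUSSO recovers the true support on a well-separated instance", {
  truth <- test_truth(q = 10, s_beta = 0.8, seed = 11)
  dat <- generate_dataset(500, 10, truth, "two_cluster", sigma2_R = 1, seed = 42)
  fit <- clusso(dat$tubules, dat$outcomes, method = "clusso", seed = 7)
  expect_identical(which(fit$beta_norm != 0), which(truth$beta_star != 0))
  met <- selection_metrics(fit$beta_norm, truth$beta_star)
  expect_identical(met$tpr, 1)
  expect_identical(met$fpr, 0)
  expect_lt(met$l1_bias, 0.1)
})

test_that("the oracle fit on noiseless data recovers support with small bias", {
  truth <- test_truth(q = 10, s_beta = 0.8, seed = 11)
  dat <- generate_dataset(500, 10, truth, "two_cluster", sigma2_eps = 0, seed = 43)
  fit <- clusso(outcomes = dat$outcomes, method = "full_info", truth = dat$truth, seed = 3)
  expect_identical(which(fit$beta_norm != 0), which(truth$beta_star != 0))
  met <- selection_metrics(fit$beta_norm, truth$beta_star)
  expect_lt(met$l1_bias, 0.05)
  ## in-sample MSE beats the null model on noiseless data
  expect_lt(fit$mse, mean((fit$y - mean(fit$y))^2))
})

test_that("every method beats the null model in-sample on noiseless data", {
  truth <- test_truth(q = 6, s_beta = 0.5, seed = 19)
  dat <- generate_dataset(120, 6, truth, "two_cluster", sigma2_eps = 0, seed = 44)
  null_mse <- mean((dat$outcomes$y - mean(dat$outcomes$y))^2)
  for (m in c("clusso", "naive")) {
    fit <- clusso(dat$tubules, dat$outcomes, method = m, seed = 5)
    expect_lt(fit$mse, null_mse)
  }
  ff <- clusso(outcomes = dat$outcomes, method = "full_info", truth = dat$truth, seed = 5)
  expect_lt(ff$mse, null_mse)
})

test_that("fits are deterministic end-to-end under a fixed seed", {
  truth <- test_truth(q = 5, s_beta = 0.4, seed = 3)
  dat <- generate_dataset(60, 5, truth, "two_cluster", seed = 21)
  for (m in c("clusso", "naive")) {
    f1 <- clusso(dat$tubules, dat$outcomes, method = m, n_folds = 3, seed = 6)
    f2 <- clusso(dat$tubules, dat$outcomes, method = m, n_folds = 3, seed = 6)
    expect_identical(f1, f2, info = m)
  }
  f1 <- clusso(outcomes = dat$outcomes, method = "full_info", truth = dat$truth,
               n_folds = 3, seed = 6)
  f2 <- clusso(outcomes = dat$outcomes, method = "full_info", truth = dat$truth,
               n_folds = 3, seed = 6)
  expect_identical(f1, f2)
})

test_that("the naive lambda path follows the all-zero-at-lambda-max convention", {
  truth <- test_truth(q = 8, s_beta = 0.5, seed = 9)
  dat <- generate_dataset(80, 8, truth, "two_cluster", seed = 23)
  fit <- clusso(dat$tubules, dat$outcomes, method = "naive", seed = 4)
  grid <- fit$cv_table$lambda
  expect_identical(length(grid), 100L)
  expect_equal(min(grid) / max(grid), 1e-4, tolerance = 1e-10)
  ## beta is identically zero at lambda_max under the (1/n) RSS objective
  withr::with_seed(77, {
    X <- matrix(rnorm(50 * 4), 50, 4)
    y <- rnorm(50)
  })
  Xs <- scale(X)
  yc <- y - mean(y)
  g <- naive_lambda_grid(Xs, yc)
  lmax <- max(g)
  gfit <- glmnet::glmnet(Xs, yc, lambda = lmax * (1 + 1e-8) / 2,
                         standardize = FALSE, intercept = FALSE)
  expect_true(all(gfit$beta == 0))
  ## any noticeably larger threshold would no longer be the smallest such lambda
  gfit2 <- glmnet::glmnet(Xs, yc, lambda = lmax * 0.8 / 2,
                          standardize = FALSE, intercept = FALSE)
  expect_gt(sum(gfit2$beta != 0), 0)
})

test_that("a single-feature naive fit recovers the slope on noiseless data", {
  withr::with_seed(13, {
    n <- 60
    sid <- sprintf("S%03d", 1:n)
    p <- rep(5, n)
    x <- rnorm(n)
    tub <- tubule_table(data.frame(subject_id = rep(sid, p),
                                   object_id = paste0("t", sequence(p)),
                                   f1 = rep(x, p)))
    out <- data.frame(subject_id = sid, y = 3 * x)
  })
  fit <- clusso(tub, out, method = "naive", seed = 2)
  ## beta is on the standardized scale: slope = beta / sd(xbar)
  expect_equal(fit$beta / sd(x), 3, tolerance = 0.01)
})

test_that("a G = 1 fit degenerates to a lasso on subject means", {
  truth <- test_truth(q = 4, s_beta = 0.5, G = 1, seed = 5)
  dat <- generate_dataset(60, 4, truth, "one_cluster", seed = 31)
  fit <- clusso(dat$tubules, dat$outcomes, method = "clusso", G = 1, seed = 3)
  expect_identical(fit$G, 1L)
  expect_equal(abs(fit$alpha), 1, tolerance = 1e-10)
  ## the single design row is exactly the per-subject feature mean
  des <- build_design(dat$tubules, rep(1L, nrow(dat$tubules)), G = 1)
  feats <- as.matrix(as.data.frame(dat$tubules)[, paste0("f", 1:4)])
  xbar <- rowsum(feats, dat$tubules$subject_id) / as.vector(table(dat$tubules$subject_id))
  expect_equal(des$X_dstar[1, , 1], unname(xbar[des$subjects[1], ]))
  expect_true(all(des$w == 1))
})

test_that("prediction resolves train-test cluster correspondence by MSE", {
  truth <- test_truth(q = 5, s_beta = 0.4, seed = 8)
  dat <- generate_dataset(80, 5, truth, "two_cluster", seed = 35)
  fit <- clusso(dat$tubules, dat$outcomes, method = "clusso", seed = 4)
  pr <- predict(fit, dat$tubules, dat$outcomes)
  expect_identical(nrow(pr$permutations), 2L)      # G = 2 -> two correspondences
  expect_identical(pr$chosen, which(apply(pr$permutations, 1, identical, y = 1:2)))
  ## in-sample identity permutation reproduces the training fitted values
  ord <- match(fit$subjects, pr$subjects)
  expect_equal(pr$predictions[ord, pr$chosen], unname(fitted(fit)), tolerance = 1e-10)
  ## the mse of the chosen correspondence matches the training mse
  expect_equal(min(pr$mse), fit$mse, tolerance = 1e-10)
  ## naive prediction has a single correspondence
  fn <- clusso(dat$tubules, dat$outcomes, method = "naive", seed = 4)
  prn <- predict(fn, dat$tubules, dat$outcomes)
  expect_identical(nrow(prn$permutations), 1L)
  expect_equal(min(prn$mse), fn$mse, tolerance = 1e-10)
  ## feature mismatch is fatal
  bad <- as.data.frame(dat$tubules); names(bad)[3] <- "other"
  expect_error(predict(fit, tubule_table(bad)), "features")
})

test_that("with true labels and growing object counts CLUSSO approaches the oracle", {
  truth <- test_truth(q = 6, s_beta = 0.5, seed = 14)
  gap <- sapply(c(40, 640), function(mu_M) {
    median(sapply(1:6, function(r) {
      dat <- generate_dataset(150, 6, truth, "two_cluster", mu_M = mu_M,
                              seed = derive_seed(60, mu_M, r))
      desC <- build_design(dat$tubules, dat$true_labels, G = 2)
      y <- dat$outcomes$y[match(desC$subjects, dat$outcomes$subject_id)]
      stdC <- standardize_design(desC, y)
      solC <- solve_multi_init(stdC$X, stdC$y, 0.5, n_inits = 3, seed = 70 + r)
      desF <- build_full_info_design(dat$truth)
      keep <- match(desC$subjects, desF$subjects)
      desF$X_dstar <- desF$X_dstar[, , keep, drop = FALSE]
      stdF <- standardize_design(desF, y)
      solF <- solve_multi_init(stdF$X, stdF$y, 0.5, n_inits = 3, seed = 70 + r)
      sum(abs(solC$beta - solF$beta))
    }))
  })
  expect_lt(gap[2], gap[1])
})
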