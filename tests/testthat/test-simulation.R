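test_that("object counts come from the moment-matched discrete uniform", {
  ## sqrt(12 * 5 + 1) = sqrt(61) ~ 7.81 -> H = 7, support {37, ..., 43}
  p <- sample_tubule_counts(2000, mu_M = 40, sigma2_M = 5, seed = 1)
  expect_setequal(sort(unique(p)), 37:43)
  ## degenerate variance collapses to a point mass at the mean
  p0 <- sample_tubule_counts(50, mu_M = 40, sigma2_M = 0.05, seed = 2)
  expect_true(all(p0 == 40L))
  ## moments: mean 40, variance (H^2 - 1)/12 = 4
  pm <- sample_tubule_counts(1e5, 40, 5, seed = 3)
  expect_lt(abs(mean(pm) - 40), 0.03)
  expect_lt(abs(var(pm) - 4), 0.06)
  ## support falling below 1 object is fatal
  expect_error(sample_tubule_counts(5, mu_M = 2, sigma2_M = 5, seed = 1), "too small")
})

test_that("the shared truth has the stated support size, value set and determinism", {
  tr <- generate_truth(10, 0.8, 2, seed = 4)
  expect_identical(sum(tr$beta_star != 0), 2L)
  expect_true(all(tr$beta_star[tr$beta_star != 0] %in% 1:4))
  expect_true(all(tr$alpha_star %in% 1:4))
  expect_identical(generate_truth(10, 0.8, 2, seed = 4), tr)
  ## full sparsity zeroes everything
  expect_true(all(generate_truth(6, 1, 2, seed = 1)$beta_star == 0))
})

test_that("zero measurement noise reproduces latent rows exactly", {
  tr <- test_truth(q = 4, s_beta = 0.5, seed = 6)
  dat <- generate_dataset(12, 4, tr, "two_cluster", sigma2_R = 0, seed = 7)
  feats <- as.matrix(as.data.frame(dat$tubules)[, paste0("f", 1:4)])
  for (r in c(1, 50, nrow(feats))) {
    i <- match(dat$tubules$subject_id[r], dat$truth$subjects)
    k <- dat$true_labels[r]
    expect_equal(unname(feats[r, ]), dat$truth$X_star[k, , i], tolerance = 1e-12)
  }
})

test_that("generator moments match the stated scenario laws", {
  tr <- test_truth(q = 2, s_beta = 0.5, seed = 8)
  dat <- generate_dataset(4000, 2, tr, "two_cluster", sigma2_R = 0, seed = 9)
  Xs <- dat$truth$X_star
  expect_equal(mean(Xs[1, , ]), 2, tolerance = 0.05)
  expect_equal(mean(Xs[2, , ]), 5, tolerance = 0.1)
  expect_equal(var(as.vector(Xs[1, , ])), 1, tolerance = 0.05)
  expect_equal(var(as.vector(Xs[2, , ])), 3, tolerance = 0.15)
  ## weights live on the stated finite set and sum to one
  expect_true(all(dat$truth$w[, 1] %in% seq(0.2, 0.8, 0.1)))
  expect_equal(rowSums(dat$truth$w), rep(1, 4000))
  ## per-subject label-1 frequency tracks w1 up to binomial noise
  f1 <- tapply(dat$true_labels == 1, dat$tubules$subject_id, mean)
  w1 <- dat$truth$w[match(names(f1), dat$truth$subjects), 1]
  expect_lt(max(abs(f1 - w1)), 0.35)
  expect_lt(mean(abs(f1 - w1)), 0.07)
})

test_that("the correlated scenario induces between-row correlation 0.5", {
  tr <- test_truth(q = 25, s_beta = 0.8, seed = 10)
  dat <- generate_dataset(4000, 25, tr, "correlated", seed = 11)
  Xs <- dat$truth$X_star
  r <- cor(as.vector(Xs[1, , ]), as.vector(Xs[2, , ]))
  expect_equal(r, 0.5, tolerance = 0.02)
  expect_equal(var(as.vector(Xs[2, , ])), 3, tolerance = 0.1)
})

test_that("the three-cluster scenario keeps all weights at least 0.2", {
  tr <- generate_truth(4, 0.5, 3, seed = 12)
  dat <- generate_dataset(500, 4, tr, "three_cluster", seed = 13)
  expect_true(all(dat$truth$w >= 0.2 - 1e-12))
  expect_equal(rowSums(dat$truth$w), rep(1, 500))
  expect_identical(dim(dat$truth$X_star)[1], 3L)
})

test_that("selection metrics count support recovery and normalize bias", {
  m <- selection_metrics(c(0.5, 0, 1.8, 0.01, 0), c(1, 0, 2, 0, 0))
  expect_identical(m$tpr, 1)
  expect_equal(m$fpr, 1 / 3)
  ## proportional estimates have zero bias
  expect_equal(selection_metrics(c(2, 0, 4, 0, 0), c(1, 0, 2, 0, 0))$l1_bias, 0)
  ## an all-zero estimate has bias 1 and zero rates
  m0 <- selection_metrics(rep(0, 10), c(3, 2, rep(0, 8)))
  expect_identical(m0$tpr, 0)
  expect_identical(m0$fpr, 0)
  expect_equal(m0$l1_bias, 1)
  ## undefined denominators are NA, not zero
  expect_true(is.na(selection_metrics(c(1, 0), c(0, 0))$tpr))
  expect_true(is.na(selection_metrics(c(1, 1), c(1, 2))$fpr))
})

test_that("the harness aggregates, reproduces and caches repetitions", {
  settings <- data.frame(n = 40, q = 4, s_beta = 0.5, scenario = "two_cluster",
                         sigma2_R = 1)
  res1 <- run_simulation(settings, methods = c("naive", "full_info"), reps = 1,
                         seed = 5, n_folds = 3, n_inits = 2)
  ## reps = 1: the summary equals the single repetition
  for (m in c("naive", "full_info")) {
    pr <- res1$per_rep[res1$per_rep$method == m, ]
    expect_identical(res1$summary$fpr[res1$summary$method == m], pr$fpr)
    expect_identical(res1$summary$mse[res1$summary$method == m], pr$mse)
  }
  ## same master seed -> identical tables
  res2 <- run_simulation(settings, methods = c("naive", "full_info"), reps = 1,
                         seed = 5, n_folds = 3, n_inits = 2)
  expect_identical(res1$summary, res2$summary)
  ## cached reruns reuse per-rep results
  cache <- withr::local_tempdir()
  res3 <- run_simulation(settings, methods = "naive", reps = 2, seed = 5,
                         n_folds = 3, cache_dir = cache)
  expect_length(list.files(cache, pattern = "csv$"), 2L)
  res4 <- run_simulation(settings, methods = "naive", reps = 2, seed = 5,
                         n_folds = 3, cache_dir = cache)
  expect_equal(res3$summary, res4$summary)
})

test_that("the one-cluster scenario drives wholesale subject dropping under G = 2", {
  tr <- generate_truth(5, 0.4, 1, seed = 14)
  dat <- generate_dataset(60, 5, tr, "one_cluster", seed = 15)
  cl <- cluster_pooled(dat$tubules, 2, "gmm", seed = 3)
  sizes <- table(factor(cl$labels, levels = 1:2))
  ## clustering a single latent subgroup is near-arbitrary: either one cluster
  ## swallows most objects, or subjects are dropped for missing a cluster
  des <- tryCatch(build_design(dat$tubules, cl, 2), error = function(e) NULL)
  skewed <- max(sizes) / sum(sizes) > 0.7
  dropped_many <- !is.null(des) && length(des$dropped) > 0.2 * 60
  expect_true(skewed || dropped_many || is.null(des))
})
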