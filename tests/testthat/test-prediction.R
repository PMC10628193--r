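# Desk-scale settings: grids, folds, repetitions and permutation counts are
# reduced relative to the defaults (which follow the full-size protocol);
# the planted/null contrasts tested here do not depend on grid resolution.

test_that("AUC is the rank statistic with tie handling", {
  expect_equal(auc_score(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc_score(c(3, 2, 1), c(1, 0, 1)), 0.5)
  expect_equal(auc_score(c(1, 1), c(0, 1)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("degenerate targets are rejected", {
  x <- matrix(rnorm(100), 20, 5)
  expect_error(svr_predict_cv(x, rep(1, 20)), "constant")
  expect_error(svm_classify_cv(x, rep(1L, 20)), "both classes")
  expect_error(svm_classify_cv(x, c(rep(0L, 18), 1L, 1L)), "at least 5")
  expect_error(svr_predict_cv(x, rnorm(20), mask = rep(FALSE, 5)),
               "no features")
})

test_that("SVR recovers a planted linear signal and reports a baseline", {
  set.seed(1)
  n <- 120
  x <- matrix(rnorm(n * 30), n, 30)
  mask <- rep(c(TRUE, FALSE), c(10, 20))
  w <- rnorm(10)
  y <- drop(x[, mask] %*% w) + rnorm(n, sd = 0.3)
  rep1 <- svr_predict_cv(x, y, mask, c_grid = c(0.3, 1),
                         outer_folds = 5, inner_folds = 3,
                         repetitions = 1, n_perm = 0, seed = 2)
  expect_gt(rep1$r, 0.6)
  expect_lt(rep1$mae, rep1$baseline_mae)
  expect_equal(rep1$baseline_mae, mean(abs(y - mean(y))))
  expect_identical(rep1$mask_mode, "masked")
  expect_identical(rep1$n_features, 10L)
  # reproducibility: identical reports for identical seeds
  rep2 <- svr_predict_cv(x, y, mask, c_grid = c(0.3, 1),
                         outer_folds = 5, inner_folds = 3,
                         repetitions = 1, n_perm = 0, seed = 2)
  expect_identical(rep1$predictions, rep2$predictions)
})

test_that("SVR on an independent target is null", {
  set.seed(3)
  x <- matrix(rnorm(100 * 20), 100, 20)
  y <- rnorm(100)
  rep0 <- svr_predict_cv(x, y, NULL, c_grid = c(0.5),
                         outer_folds = 5, inner_folds = 3,
                         repetitions = 1, n_perm = 30, seed = 4)
  expect_lt(abs(rep0$r), 0.3)
  expect_gt(rep0$permuted_p, 0.05)
})

test_that("SVM separates shifted groups and stays at chance under the null", {
  sep <- generate_two_group_cohort(c(20, 20), 3, 8, noise_sd = 0.3,
                                   latent_sd = 0.3, seed = 5)
  mask <- abs(sep$true_salience_x) > 0
  cls <- svm_classify_cv(sep$edges$values, sep$labels, mask,
                         c_grid = 2^c(-1, 3), gamma_grid = 2^c(-7, -3),
                         outer_folds = 5, inner_folds = 3,
                         repetitions = 1, n_perm = 0, seed = 6)
  expect_gt(cls$accuracy, 0.9)
  expect_gt(cls$auc, 0.95)
  expect_true(cls$meaningful)
  nul <- generate_two_group_cohort(c(20, 20), 0, 8, seed = 7)
  cls0 <- svm_classify_cv(nul$edges$values, nul$labels,
                          abs(nul$true_salience_x) > 0,
                          c_grid = 2^c(-1, 3), gamma_grid = 2^c(-7, -3),
                          outer_folds = 5, inner_folds = 3,
                          repetitions = 1, n_perm = 0, seed = 8)
  expect_lt(abs(cls0$accuracy - 0.5), 0.25)
  expect_false(cls0$meaningful && cls0$accuracy > 0.75)
})

test_that("feature-set comparison is descriptive and guarded", {
  set.seed(9)
  x <- matrix(rnorm(80 * 10), 80, 10)
  y <- drop(x[, 1:3] %*% c(1, -1, 0.5)) + rnorm(80, sd = 0.4)
  shared <- list(c_grid = c(0.5), outer_folds = 5, inner_folds = 3,
                 repetitions = 1, n_perm = 0, seed = 10)
  rep_a <- do.call(svr_predict_cv, c(list(x, y, rep(TRUE, 10)), shared))
  rep_b <- do.call(svr_predict_cv, c(list(x, y, NULL), shared))
  cmp <- compare_feature_sets(rep_a, rep_b)
  expect_identical(cmp$metric, c("r", "mae"))
  expect_equal(cmp$difference, rep(0, 2), tolerance = 1e-10) # identical features
  rep_c <- do.call(svr_predict_cv, c(list(x, y, c(rep(TRUE, 3), rep(FALSE, 7))),
                                     shared))
  cmp2 <- compare_feature_sets(rep_c, rep_b)
  expect_true(all(is.finite(cmp2$masked)) && all(is.finite(cmp2$whole_brain)))
  bad <- rep_b
  bad$seed <- 999L
  expect_error(compare_feature_sets(rep_a, bad), "invalid comparison")
})
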