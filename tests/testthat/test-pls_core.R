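test_that("identical blocks give a perfect first LV", {
  set.seed(1)
  x <- scale(matrix(rnorm(40), 20, 2))
  fit <- fit_pls(x, x)
  expect_equal(fit$composite_x[, 1], fit$composite_y[, 1], tolerance = 1e-10)
  expect_equal(cor(fit$composite_x[, 1], fit$composite_y[, 1]), 1,
               tolerance = 1e-10)
})

test_that("covariance explained is the normalized squared spectrum", {
  expect_equal(covariance_explained(c(2, 1, 1)), c(4, 1, 1) / 6)
  expect_equal(covariance_explained(5), 1)
  expect_equal(covariance_explained(c(2, 1)), covariance_explained(c(6, 3)))
  expect_error(covariance_explained(c(0, 0)), "all-zero")
  # near-diagonal cross-correlation: saliences align with coordinate axes
  set.seed(2)
  n <- 4000
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- scale(cbind(z1 + 0.5 * rnorm(n), z2 + 2 * rnorm(n)))
  y <- scale(cbind(z1 + 0.5 * rnorm(n), z2 + 2 * rnorm(n)))
  fit <- fit_pls(x, y)
  expect_gt(abs(fit$saliences_y[1, 1]), 0.99)
  expect_gt(abs(fit$saliences_y[2, 2]), 0.99)
})

test_that("leading salience pair attains the grid-search maximum", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(4:10, 1); e <- sample(3:6, 1); p <- sample(2:3, 1)
    x <- scale(matrix(rnorm(n * e), n, e))
    y <- scale(matrix(rnorm(n * p), n, p))
    fit <- fit_pls(x, y)
    r <- crossprod(y, x) / (n - 1)
    expect_lt(abs(fit$singular_values[1] - grid_search_max(r)), 1e-3)
  }
})

test_that("model invariants hold: unit norms, orthogonality, proportions", {
  set.seed(4)
  x <- scale(matrix(rnorm(30 * 7), 30, 7))
  y <- scale(matrix(rnorm(30 * 4), 30, 4))
  fit <- fit_pls(x, y)
  expect_equal(colSums(fit$saliences_x^2), rep(1, 4), tolerance = 1e-10)
  expect_equal(colSums(fit$saliences_y^2), rep(1, 4), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(fit$saliences_x) - diag(4))), 1e-10)
  expect_lt(max(abs(crossprod(fit$saliences_y) - diag(4))), 1e-10)
  expect_true(all(diff(fit$singular_values) <= 1e-12))
  expect_equal(sum(covariance_explained(fit$singular_values)), 1,
               tolerance = 1e-12)
  # sign convention: largest-magnitude behavioural salience entry positive,
  # and re-applying the convention changes nothing (idempotence)
  top <- apply(abs(fit$saliences_y), 2, which.max)
  expect_true(all(fit$saliences_y[cbind(top, 1:4)] > 0))
  refit <- connpls:::fix_signs(fit$saliences_y, fit$saliences_x)
  expect_equal(refit$y, fit$saliences_y)
  expect_equal(refit$x, fit$saliences_x)
})

test_that("permutation p-values use the add-one rule and calibrate", {
  # planted signal: no permutation exceeds the observed first singular value
  co <- generate_cohort(300, 8, 6, 0.8, seed = 11)
  blocks <- residualized_blocks(co)
  pt <- permutation_test_lvs(blocks$x, blocks$y, n_perm = 100, seed = 12)
  expect_equal(pt$lv_pvalues[1], 1 / 101)
  expect_true(all(pt$lv_pvalues > 0))
  expect_error(permutation_test_lvs(blocks$x, blocks$y, n_perm = 5), ">= 10")
  # reduced type-I check (the full 1000x200 version is an acceptance test)
  rej <- 0
  for (s in 1:50) {
    co0 <- generate_cohort(100, 6, 5, 0, confound_effects = rep(0, 4),
                           seed = 300 + s)
    p <- permutation_test_lvs(scale(co0$edges$values),
                              scale(co0$behavior$values),
                              n_perm = 100, seed = s, k = 1)$lv_pvalues[1]
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej, 0)
  expect_lte(rej, 8) # binomial(50, 0.05) upper tail
})

test_that("confound contamination inflates raw PLS but not residualized PLS", {
  raw_rej <- res_rej <- 0
  for (s in 1:20) {
    co <- generate_cohort(150, 10, 8, 0, confound_effects = c(1, 1, 1, 1),
                          seed = 500 + s)
    raw_p <- permutation_test_lvs(scale(co$edges$values),
                                  scale(co$behavior$values),
                                  n_perm = 100, seed = s, k = 1)$lv_pvalues[1]
    blocks <- residualized_blocks(co)
    res_p <- permutation_test_lvs(blocks$x, blocks$y,
                                  n_perm = 100, seed = s, k = 1)$lv_pvalues[1]
    raw_rej <- raw_rej + (raw_p < 0.05)
    res_rej <- res_rej + (res_p < 0.05)
  }
  expect_gte(raw_rej, 15) # spurious LV1 well above the nominal rate
  expect_lte(res_rej, 5)
})

test_that("bootstrap loadings: sign alignment and duplicate-column symmetry", {
  set.seed(21)
  x <- scale(matrix(rnorm(60 * 5), 60, 5))
  ybase <- matrix(rnorm(60 * 2), 60, 2)
  y <- scale(cbind(ybase, ybase[, 1])) # duplicated behavioural column
  fit <- fit_pls(x, y)
  bt <- bootstrap_loadings(x, y, fit, n_boot = 50, seed = 22)
  expect_equal(bt$loading_sd_y[1, ], bt$loading_sd_y[3, ], tolerance = 1e-10)
  expect_true(all(bt$loading_sd_x >= 0))
  # a model with jointly flipped saliences yields identical SDs
  flipped <- fit
  flipped$saliences_x <- -fit$saliences_x
  flipped$saliences_y <- -fit$saliences_y
  bt2 <- bootstrap_loadings(x, y, flipped, n_boot = 50, seed = 22)
  expect_equal(bt2$loading_sd_y, bt$loading_sd_y, tolerance = 1e-10)
})

test_that("bootstrap z separates planted from null behaviours", {
  co <- generate_cohort(300, 10, 12, 0.8, support_fraction_y = 0.5, seed = 9)
  blocks <- residualized_blocks(co)
  fit <- fit_pls(blocks$x, blocks$y)
  bt <- bootstrap_loadings(blocks$x, blocks$y, fit, n_boot = 200, seed = 10)
  support <- abs(co$true_salience_y) > 0
  expect_gt(min(abs(bt$bootstrap_z_y[support, 1])), 3)
  expect_lt(max(abs(bt$bootstrap_z_y[!support, 1])), 3)
})

test_that("cross-validation generalizes planted structure and stays null-safe", {
  co <- generate_cohort(400, 10, 8, 0.8, seed = 21)
  cv <- cross_validate_pls(co$edges$values, co$behavior$values,
                           co$behavior$confounds, folds = 10,
                           repetitions = 5, n_perm_cv = 100, seed = 22)
  expect_gt(cv$mean_test_r[1], 0.3)
  expect_lte(cv$permuted_p[1], 0.01)
  co0 <- generate_cohort(200, 8, 6, 0, seed = 23)
  cv0 <- cross_validate_pls(co0$edges$values, co0$behavior$values,
                            co0$behavior$confounds, folds = 10,
                            repetitions = 10, n_perm_cv = 0, seed = 24)
  expect_lt(abs(cv0$mean_test_r[1]), 0.05)
  expect_error(
    cross_validate_pls(co0$edges$values[1:12, ], co0$behavior$values[1:12, ],
                       folds = 10, repetitions = 1, n_perm_cv = 0, seed = 1),
    "fewer than 3")
})

test_that("projection reproduces training scores and transfers planted signal", {
  co <- generate_cohort(600, 10, 8, 0.8, seed = 31)
  blocks <- residualized_blocks(co)
  h1 <- 1:300; h2 <- 301:600
  xtr <- scale(blocks$x[h1, ]); ytr <- scale(blocks$y[h1, ])
  fit <- fit_pls(xtr, ytr)
  self <- project_pls(fit, xtr, ytr, n_perm = 0)
  expect_equal(self$composite_x, fit$composite_x, tolerance = 1e-10)
  # held-out half shares the planted latent: significant positive transfer
  tr <- project_pls(fit, scale(blocks$x[h2, ]), scale(blocks$y[h2, ]),
                    n_perm = 100, seed = 32)
  expect_gt(tr$r[1], 0.3)
  expect_lte(tr$p[1], 0.05)
  # independent null cohorts: no transfer (aggregated over draws, since a
  # single projection r has sd ~ 1/sqrt(n) and lone 3-sigma draws happen)
  null_r <- null_p <- numeric(5)
  for (s in 1:5) {
    co0 <- generate_cohort(300, 10, 8, 0, seed = 33 + 100 * s)
    b0 <- residualized_blocks(co0)
    tr0 <- project_pls(fit, scale(b0$x), scale(b0$y), n_perm = 100, seed = 34)
    null_r[s] <- tr0$r[1]
    null_p[s] <- tr0$p[1]
  }
  expect_lt(mean(abs(null_r)), 0.12)
  expect_gte(sum(null_p > 0.05), 3)
  expect_error(project_pls(fit, b0$x[, 1:10], b0$y, n_perm = 0), "schema")
})

test_that("model comparison is sign-aligned and recovers split-half stability", {
  co <- generate_cohort(600, 10, 12, 0.8, seed = 41)
  blocks <- residualized_blocks(co)
  a <- fit_pls(scale(blocks$x[1:300, ]), scale(blocks$y[1:300, ]))
  b <- fit_pls(scale(blocks$x[301:600, ]), scale(blocks$y[301:600, ]))
  self <- compare_pls_models(a, a)
  expect_equal(self$salience_r_y, 1, tolerance = 1e-12)
  expect_equal(self$loading_r_x, 1, tolerance = 1e-12)
  flip <- a
  flip$saliences_x <- -a$saliences_x
  flip$saliences_y <- -a$saliences_y
  flip$loadings_x <- -a$loadings_x
  flip$loadings_y <- -a$loadings_y
  fcmp <- compare_pls_models(a, flip)
  expect_equal(fcmp$salience_r_y, 1, tolerance = 1e-12)
  cmp <- compare_pls_models(a, b)
  expect_gt(cmp$salience_r_y, 0.8)
})

test_that("first principal component tracks a spiked covariance direction", {
  set.seed(51)
  n <- 500
  spike <- rnorm(n)
  # centred but not column-rescaled, so the spike direction is preserved
  y <- scale(outer(spike, c(3, 2, 1, 0.5)) + matrix(rnorm(n * 4), n, 4) * 0.3,
             scale = FALSE)
  pc <- first_principal_component(y)
  truth <- c(3, 2, 1, 0.5) / sqrt(sum(c(3, 2, 1, 0.5)^2))
  expect_gt(abs(sum(pc$component * truth)), 0.99)
  expect_equal(first_principal_component(y, pc$component)$correlation, 1,
               tolerance = 1e-10)
  # isotropic input still yields a unit vector (contract only)
  iso <- first_principal_component(scale(matrix(rnorm(200), 50, 4)))
  expect_equal(sum(iso$component^2), 1, tolerance = 1e-10)
})

test_that("planted saliences are recovered across seeds", {
  ok <- 0
  for (s in 1:10) {
    co <- generate_cohort(500, 20, 36, 0.8, seed = 600 + s)
    blocks <- residualized_blocks(co)
    fit <- fit_pls(blocks$x, blocks$y, k = 1)
    ok <- ok + (abs(cor(fit$saliences_y[, 1], co$true_salience_y)) > 0.9)
  }
  expect_gte(ok, 9) # the 100-seed version is an acceptance test
})
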