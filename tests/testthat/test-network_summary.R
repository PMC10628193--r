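test_that("edge thresholding applies Benjamini-Hochberg at the stated level", {
  # hand BH: thresholds (0.0125, 0.025, 0.0375, 0.05) keep the first three
  p <- c(0.001, 0.011, 0.02, 0.8)
  loading <- c(0.5, -0.4, 0.3, 0.1)
  map <- threshold_edges(loading, p, q_threshold = 0.05)
  expect_identical(map$mask, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(map$sign, c(1, -1, 1, 0))
  expect_identical(map$mask, bh_reject(p, 0.05))
  expect_identical(threshold_edges(loading, rep(1, 4))$mask, rep(FALSE, 4))
  expect_identical(threshold_edges(loading, rep(1e-6, 4))$mask, rep(TRUE, 4))
  expect_error(threshold_edges(loading, c(0.1, 0.2, 0.3, 1.2)), "\\[0, 1\\]")
  # property: agrees with the hand step-up rule on random inputs
  set.seed(1)
  for (i in 1:20) {
    pr <- runif(50)^2
    expect_identical(threshold_edges(rnorm(50), pr)$mask, bh_reject(pr, 0.05))
  }
})

test_that("edge p-values follow the loading-correlation t distribution", {
  co <- generate_cohort(80, 8, 6, 0.5, seed = 2)
  blocks <- residualized_blocks(co)
  fit <- fit_pls(blocks$x, blocks$y)
  ep <- edge_pvalues(fit, lv = 1)
  # oracle: cor.test on a few edges
  for (j in c(1, 7, 20)) {
    ct <- cor.test(blocks$x[, j], fit$composite_x[, 1])
    expect_equal(ep$p_value[j], ct$p.value, tolerance = 1e-8)
  }
  bt <- bootstrap_loadings(blocks$x, blocks$y, fit, n_boot = 50, seed = 3)
  epz <- edge_pvalues(fit, lv = 1, method = "bootstrap_z", boot = bt)
  expect_true(all(epz$p_value >= 0 & epz$p_value <= 1))
})

test_that("mask summaries reproduce count/percentage arithmetic", {
  s <- summarize_mask(list(loading = numeric(10), sign = integer(10)),
                      n_total_edges = 10)
  expect_identical(s$n_sig, 0L)
  expect_equal(s$pct_sig, 0)
  full <- list(loading = rep(0.2, 10), sign = rep(1L, 10))
  expect_equal(summarize_mask(full, 10)$pct_sig, 100)
  expect_equal(summarize_mask(full, 10)$pct_pos, 100)
})

test_that("network block averages match hand-enumerated means", {
  regions <- region_table(0:3, paste0("R", 0:3),
                          c("A", "A", "B", "B"), c("L", "R", "L", "R"),
                          x = 1:4, y = 1:4, z = 1:4)
  # canonical edge order for n=4: (0,1) (0,2) (0,3) (1,2) (1,3) (2,3)
  vals <- c(10, 1, 2, 3, 4, 20)
  blocks <- network_block_average(vals, regions)
  expect_equal(blocks["A", "A"], 10)
  expect_equal(blocks["B", "B"], 20)
  expect_equal(blocks["A", "B"], mean(c(1, 2, 3, 4)))
  expect_equal(blocks["B", "A"], blocks["A", "B"])
  # constant edge values fill every nonempty block with the constant
  expect_true(all(network_block_average(rep(7, 6), regions) == 7))
  # two singleton networks: within-network blocks are empty, hence NA
  r2 <- region_table(0:1, c("a", "b"), c("A", "B"), c("L", "R"),
                     x = 1:2, y = 1:2, z = 1:2)
  b2 <- network_block_average(5, r2)
  expect_true(is.na(b2["A", "A"]) && is.na(b2["B", "B"]))
  expect_equal(b2["A", "B"], 5)
  # masked averaging drops excluded edges
  masked <- network_block_average(vals, regions,
                                  mask = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_true(is.na(masked["A", "B"]))
  expect_equal(masked["A", "A"], 10)
})

test_that("region importance sums incident significant loadings by sign", {
  # single positive edge (0, 1) with loading 0.4 in a 4-region world
  map1 <- list(loading = c(0.4, 0, 0, 0, 0, 0),
               sign = c(1, 0, 0, 0, 0, 0))
  imp1 <- region_importance(map1, 4)
  expect_equal(imp1$positive_score, c(0.4, 0.4, 0, 0))
  expect_equal(imp1$negative_score, rep(0, 4))
  # star: all significant edges touch region 0
  vals <- numeric(6); sgn <- numeric(6)
  star_edges <- edge_index(c(0, 0, 0), c(1, 2, 3), 4)
  vals[star_edges + 1] <- c(0.1, 0.2, 0.3)
  sgn[star_edges + 1] <- 1
  vals[6] <- 0.4; sgn[6] <- 1 # (2,3) closes the 4th edge of the example
  imp_star <- region_importance(list(loading = vals, sign = sgn), 4)
  expect_equal(imp_star$positive_score[1], 0.6)
  expect_identical(imp_star$degree_pos[1], 3L)
  # conservation identity on random maps: sum of region scores is twice the
  # summed significant |loadings| (each edge counted at both endpoints)
  set.seed(4)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    e <- count_edges(n)
    loading <- rnorm(e)
    sgn <- ifelse(runif(e) < 0.4, sign(loading), 0)
    imp <- region_importance(list(loading = loading, sign = sgn), n)
    expect_equal(sum(imp$positive_score),
                 2 * sum(abs(loading)[sgn > 0]), tolerance = 1e-12)
    expect_equal(sum(imp$negative_score),
                 2 * sum(abs(loading)[sgn < 0]), tolerance = 1e-12)
  }
})

test_that("top_nodes ranks descending with id tie-breaks", {
  imp <- list(positive_score = c(0, 5, 5, 1), negative_score = c(1, 0, 0, 2),
              degree_pos = c(0L, 2L, 1L, 1L), degree_neg = c(1L, 0L, 0L, 3L))
  top <- top_nodes(imp, k = 2)
  expect_identical(top$region_id, c(1L, 2L)) # tie at 5 broken by id
  expect_identical(top_nodes(imp, k = 4)$region_id[4], 0L)
  expect_identical(top_nodes(imp, k = 1, side = "negative")$region_id, 3L)
  expect_error(top_nodes(imp, k = 9), "exceeds")
  # brute-force sort oracle on random scores
  set.seed(5)
  scores <- runif(30)
  impr <- list(positive_score = scores, negative_score = scores,
               degree_pos = integer(30), degree_neg = integer(30))
  expect_identical(top_nodes(impr, k = 30)$region_id,
                   (0:29)[order(-scores, 0:29)])
  # unweighted mode ranks by degree
  expect_identical(top_nodes(imp, k = 1, weighted = FALSE)$region_id, 1L)
})
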