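# Behavioural PLS. The cross-correlation matrix R = Y'X / (n - 1) of the two
# standardized blocks is decomposed by SVD, R = U S V'; each latent variable
# (LV) pairs a behavioural salience (column of U) with an edge salience
# (column of V), ranked by covariance explained s_k^2 / sum s^2. Composite
# scores are the projections X V and Y U; loadings are the Pearson
# correlations of raw features with their block's composite. Inference is
# nonparametric: row permutations of Y for LV significance, subject
# bootstrap for loading stability, and repeated k-fold cross-validation with
# in-fold residualization for generalizability.

standardize_block <- function(m, label) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sds <- col_sds(m)
  if (any(sds < 1e-12))
    stopf("invalid input: constant column(s) in %s block", label)
  ok <- max(abs(mu)) < 1e-8 && max(abs(sds - 1)) < 1e-8
  if (!ok) {
    warning(sprintf("%s block not standardized; re-standardizing", label),
            call. = FALSE)
    m <- scale_cols(m, mu, sds)
  }
  m
}

# flip each LV pair so the largest-magnitude behavioural salience entry is
# positive; idempotent, and always applied to (u_k, v_k) jointly
fix_signs <- function(sal_y, sal_x) {
  for (k in seq_len(ncol(sal_y))) {
    top <- which.max(abs(sal_y[, k]))
    if (sal_y[top, k] < 0) {
      sal_y[, k] <- -sal_y[, k]
      sal_x[, k] <- -sal_x[, k]
    }
  }
  list(y = sal_y, x = sal_x)
}

#' Fit a behavioural PLS model
#'
#' @param x Subjects x E edge block (standardized; re-standardized with a
#'   warning otherwise).
#' @param y Subjects x P behaviour block (same contract).
#' @param k Number of LVs to keep, or "all" (min(P, E, n-1)).
#' @return A `pls_model` with saliences, singular values, covariance
#'   explained, composite scores and loadings. See [permutation_test_lvs()],
#'   [bootstrap_loadings()], [cross_validate_pls()] for inference.
#' @export
fit_pls <- function(x, y, k = "all") {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stopf("blocks must be row-aligned")
  n <- nrow(x)
  if (n < 3) stopf("invalid input: need at least 3 subjects")
  x <- standardize_block(x, "edge")
  y <- standardize_block(y, "behaviour")
  kmax <- min(ncol(x), ncol(y), n - 1L)
  k <- if (identical(k, "all")) kmax else min(as.integer(k), kmax)
  r <- crossprod(y, x) / (n - 1)
  sv <- svd(r, nu = k, nv = k)
  s <- fix_signs(sv$u, sv$v)
  composite_x <- x %*% s$x
  composite_y <- y %*% s$y
  structure(list(
    saliences_x = s$x,
    saliences_y = s$y,
    singular_values = sv$d[seq_len(k)],
    covariance_explained = covariance_explained(sv$d)[seq_len(k)],
    composite_x = composite_x,
    composite_y = composite_y,
    loadings_x = stats::cor(x, composite_x),
    loadings_y = stats::cor(y, composite_y),
    lv_pvalues = NULL,
    lv_qvalues = NULL,
    n_subjects = n
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d subjects, %d edges x %d measures, %d LVs\n",
              x$n_subjects, nrow(x$saliences_x), nrow(x$saliences_y),
              length(x$singular_values)))
  cat("  covariance explained:",
      paste(sprintf("%.1f%%", 100 * x$covariance_explained), collapse = " "),
      "\n")
  if (!is.null(x$lv_pvalues))
    cat("  permutation p:", paste(signif(x$lv_pvalues, 3), collapse = " "), "\n")
  invisible(x)
}

#' Proportion of cross-block covariance explained per LV
#'
#' @param singular_values Nonnegative singular values.
#' @return `s_k^2 / sum(s^2)`; sums to 1.
#' @export
covariance_explained <- function(singular_values) {
  if (any(singular_values < 0)) stopf("singular values must be nonnegative")
  tot <- sum(singular_values^2)
  if (tot == 0) stopf("undefined: all-zero singular spectrum")
  singular_values^2 / tot
}

# singular values of the cross-correlation of standardized blocks
cross_singular_values <- function(x, y, k) {
  svd(crossprod(y, x) / (nrow(x) - 1), nu = 0, nv = 0)$d[seq_len(k)]
}

#' Permutation test for LV significance
#'
#' Rows of Y are permuted uniformly (X fixed); each permutation is refit and
#' singular values are matched to observed LVs by rank order. Add-one
#' p-values `(1 + #exceedances) / (n_perm + 1)` are never exactly zero;
#' q-values are Benjamini-Hochberg across LVs.
#'
#' @param x,y Standardized blocks (as passed to [fit_pls()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param k Number of LVs tested ("all" by default).
#' @return List with `lv_pvalues`, `lv_qvalues`, `observed`, `n_perm`.
#' @export
permutation_test_lvs <- function(x, y, n_perm = 1000, seed = 1L, k = "all") {
  if (!is_count(n_perm) || n_perm < 10) stopf("n_perm must be >= 10")
  x <- standardize_block(as.matrix(x), "edge")
  y <- standardize_block(as.matrix(y), "behaviour")
  n <- nrow(x)
  kmax <- min(ncol(x), ncol(y), n - 1L)
  k <- if (identical(k, "all")) kmax else min(as.integer(k), kmax)
  obs <- cross_singular_values(x, y, k)
  exceed <- integer(k)
  for (b in seq_len(n_perm)) {
    perm <- with_seed(child_seed(seed, "perm", b), sample.int(n))
    d <- cross_singular_values(x, y[perm, , drop = FALSE], k)
    exceed <- exceed + (d >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  list(lv_pvalues = p,
       lv_qvalues = stats::p.adjust(p, method = "BH"),
       observed = obs, n_perm = n_perm, seed = seed)
}

#' Bootstrap stability of PLS loadings
#'
#' Subjects are resampled with replacement and the model refit; each
#' bootstrap LV's sign is aligned to the original by the inner product of
#' behavioural saliences before loadings are accumulated. Returns per-feature
#' loading standard deviations and z = loading / sd.
#'
#' @param x,y The blocks the model was fitted on.
#' @param model A `pls_model` from [fit_pls()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return A `bootstrap_result` with `loading_sd_x`, `loading_sd_y`,
#'   `bootstrap_z_x`, `bootstrap_z_y`, `n_boot`, `n_skipped`.
#' @export
bootstrap_loadings <- function(x, y, model, n_boot = 1000, seed = 1L) {
  x <- standardize_block(as.matrix(x), "edge")
  y <- standardize_block(as.matrix(y), "behaviour")
  n <- nrow(x)
  k <- length(model$singular_values)
  sum_x <- sum2_x <- matrix(0, ncol(x), k)
  sum_y <- sum2_y <- matrix(0, ncol(y), k)
  cnt_x <- matrix(0, ncol(x), k)
  cnt_y <- matrix(0, ncol(y), k)
  n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- with_seed(child_seed(seed, "boot", b),
                     sample.int(n, replace = TRUE))
    xb <- x[idx, , drop = FALSE]
    yb <- y[idx, , drop = FALSE]
    sdx <- col_sds(xb); sdy <- col_sds(yb)
    if (any(sdx < 1e-12) || any(sdy < 1e-12)) {
      # a constant resampled column makes its loadings undefined; skip the
      # replicate for those features and report the count
      n_skipped <- n_skipped + 1L
    }
    xb <- scale_cols(xb, colMeans(xb), pmax(sdx, 1e-12))
    yb <- scale_cols(yb, colMeans(yb), pmax(sdy, 1e-12))
    sv <- svd(crossprod(yb, xb) / (n - 1), nu = k, nv = k)
    # align to the original fit by behavioural salience inner product
    flip <- sign(colSums(sv$u * model$saliences_y[, seq_len(k), drop = FALSE]))
    flip[flip == 0] <- 1
    su <- sweep(sv$u, 2L, flip, "*")
    sx <- sweep(sv$v, 2L, flip, "*")
    lx <- stats::cor(xb, xb %*% sx)
    ly <- stats::cor(yb, yb %*% su)
    okx <- sdx >= 1e-12; oky <- sdy >= 1e-12
    lx[!okx, ] <- 0; ly[!oky, ] <- 0
    sum_x <- sum_x + lx; sum2_x <- sum2_x + lx^2
    sum_y <- sum_y + ly; sum2_y <- sum2_y + ly^2
    cnt_x <- cnt_x + okx; cnt_y <- cnt_y + oky
  }
  boot_sd <- function(s, s2, cnt) {
    cnt[cnt < 2] <- 2
    v <- (s2 - s^2 / cnt) / (cnt - 1)
    v[v < 0] <- 0 # guard tiny negative float residue
    sqrt(v)
  }
  sd_x <- boot_sd(sum_x, sum2_x, cnt_x)
  sd_y <- boot_sd(sum_y, sum2_y, cnt_y)
  structure(list(
    loading_sd_x = sd_x,
    loading_sd_y = sd_y,
    bootstrap_z_x = model$loadings_x[, seq_len(k), drop = FALSE] /
      ifelse(sd_x > 0, sd_x, NA_real_),
    bootstrap_z_y = model$loadings_y[, seq_len(k), drop = FALSE] /
      ifelse(sd_y > 0, sd_y, NA_real_),
    n_boot = n_boot, n_skipped = n_skipped, seed = seed
  ), class = "bootstrap_result")
}

# one repeated-CV pass; returns per-(repetition, fold, LV) test correlations
cv_pass <- function(x_raw, y_raw, confounds, folds, repetitions, seed,
                    stream_offset = 0L, k = 2L) {
  n <- nrow(x_raw)
  kmax <- min(ncol(x_raw), ncol(y_raw), k)
  out <- array(NA_real_, c(repetitions, folds, kmax))
  for (rep_i in seq_len(repetitions)) {
    assign_idx <- with_seed(child_seed(seed, "fold", stream_offset + rep_i),
                            sample(rep_len(seq_len(folds), n)))
    for (f in seq_len(folds)) {
      test <- assign_idx == f
      if (sum(test) < 3 || sum(!test) < 3)
        stopf("fold with fewer than 3 subjects; reduce `folds`")
      ctr <- if (is.null(confounds)) NULL else confounds[!test, , drop = FALSE]
      cte <- if (is.null(confounds)) NULL else confounds[test, , drop = FALSE]
      rx <- fit_residualizer(x_raw[!test, , drop = FALSE], ctr)
      ry <- fit_residualizer(y_raw[!test, , drop = FALSE], ctr)
      xtr <- apply_residualizer(rx, x_raw[!test, , drop = FALSE], ctr)
      ytr <- apply_residualizer(ry, y_raw[!test, , drop = FALSE], ctr)
      xte <- apply_residualizer(rx, x_raw[test, , drop = FALSE], cte)
      yte <- apply_residualizer(ry, y_raw[test, , drop = FALSE], cte)
      sv <- svd(crossprod(ytr, xtr) / (sum(!test) - 1), nu = kmax, nv = kmax)
      cx <- xte %*% sv$v
      cy <- yte %*% sv$u
      for (kk in seq_len(kmax)) {
        out[rep_i, f, kk] <- suppressWarnings(stats::cor(cx[, kk], cy[, kk]))
      }
    }
  }
  out
}

#' Leakage-safe repeated k-fold cross-validation of PLS generalizability
#'
#' Per repetition and fold, confound residualization and standardization are
#' fitted on the training folds only and applied to the held-out fold; PLS
#' is fitted on training data and the test fold is projected onto the
#' training saliences. The reported statistic is the Pearson correlation
#' between test-fold edge and behaviour composite scores, averaged over
#' folds x repetitions. Significance comes from repeating the whole
#' procedure with Y rows shuffled.
#'
#' @param x_raw,y_raw Raw (unresidualized) blocks.
#' @param confounds Subjects x Q confound matrix (or NULL).
#' @param folds Number of folds (default 10).
#' @param repetitions Repetitions of the fold split (default 200).
#' @param n_perm_cv Whole-CV permutations for the p-value (default 100; each
#'   permutation is itself a full repeated CV, so this is a cost/precision
#'   trade-off).
#' @param seed RNG seed.
#' @param perm_repetitions Repetitions used inside each permutation
#'   (default 1) — the permuted statistic is still a mean over
#'   folds x repetitions.
#' @param k Number of leading LVs to track (default 2).
#' @return A `cv_result` with `test_r` (repetitions x folds x LV array),
#'   `mean_test_r` per LV, `permuted_p` per LV, and settings.
#' @export
cross_validate_pls <- function(x_raw, y_raw, confounds = NULL, folds = 10,
                               repetitions = 200, n_perm_cv = 100, seed = 1L,
                               perm_repetitions = 1L, k = 2L) {
  x_raw <- as.matrix(x_raw); y_raw <- as.matrix(y_raw)
  if (nrow(x_raw) != nrow(y_raw)) stopf("blocks must be row-aligned")
  n <- nrow(x_raw)
  obs <- cv_pass(x_raw, y_raw, confounds, folds, repetitions, seed, k = k)
  mean_r <- apply(obs, 3L, mean, na.rm = TRUE)
  permuted_p <- rep(NA_real_, length(mean_r))
  if (n_perm_cv > 0) {
    exceed <- numeric(length(mean_r))
    for (b in seq_len(n_perm_cv)) {
      perm <- with_seed(child_seed(seed, "cvperm", b), sample.int(n))
      pr <- cv_pass(x_raw, y_raw[perm, , drop = FALSE], confounds,
                    folds, perm_repetitions, seed,
                    stream_offset = 1000L + b * max(perm_repetitions, 1L),
                    k = k)
      pm <- apply(pr, 3L, mean, na.rm = TRUE)
      exceed <- exceed + (pm >= mean_r)
    }
    permuted_p <- (1 + exceed) / (n_perm_cv + 1)
  }
  structure(list(test_r = obs, mean_test_r = mean_r, permuted_p = permuted_p,
                 folds = folds, repetitions = repetitions,
                 n_perm_cv = n_perm_cv, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d repetitions\n", x$folds, x$repetitions))
  cat("  mean test r:", paste(sprintf("%.3f", x$mean_test_r), collapse = " "), "\n")
  cat("  permuted p:", paste(signif(x$permuted_p, 3), collapse = " "), "\n")
  invisible(x)
}

#' Project a new cohort onto learned saliences
#'
#' Composite scores are `X_new V` and `Y_new U` (unscaled projection;
#' composite correlations are invariant to per-LV rescaling); per-LV Pearson
#' r between them is tested by shuffling the rows of `y_new`.
#'
#' @param model A `pls_model`.
#' @param x_new,y_new New blocks, residualized/standardized by the caller's
#'   chosen policy; column dimensions must match the model.
#' @param n_perm Permutations for the r p-value (default 1000).
#' @param seed RNG seed.
#' @return List with `composite_x`, `composite_y`, `r` and `p` per LV.
#' @export
project_pls <- function(model, x_new, y_new, n_perm = 1000, seed = 1L) {
  x_new <- as.matrix(x_new); y_new <- as.matrix(y_new)
  if (ncol(x_new) != nrow(model$saliences_x) ||
      ncol(y_new) != nrow(model$saliences_y))
    stopf("schema error: new data dimensions do not match the model")
  if (nrow(x_new) != nrow(y_new)) stopf("blocks must be row-aligned")
  cx <- x_new %*% model$saliences_x
  cy <- y_new %*% model$saliences_y
  k <- ncol(cx)
  r <- vapply(seq_len(k), function(kk) stats::cor(cx[, kk], cy[, kk]),
              numeric(1))
  p <- rep(NA_real_, k)
  if (n_perm > 0) {
    exceed <- numeric(k)
    n <- nrow(y_new)
    for (b in seq_len(n_perm)) {
      perm <- with_seed(child_seed(seed, "project", b), sample.int(n))
      cyp <- cy[perm, , drop = FALSE]
      rp <- vapply(seq_len(k), function(kk) stats::cor(cx[, kk], cyp[, kk]),
                   numeric(1))
      exceed <- exceed + (abs(rp) >= abs(r))
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  list(composite_x = cx, composite_y = cy, r = r, p = p,
       n_perm = n_perm, seed = seed)
}

#' Compare saliences and loadings between two fits
#'
#' Pearson correlations between matched LV vectors after sign alignment
#' (replication-style comparison of discovery vs replication fits).
#'
#' @param a,b `pls_model`s on the same feature spaces.
#' @param lv LV index to compare (default 1).
#' @return List with `salience_r_x`, `salience_r_y`, `loading_r_x`,
#'   `loading_r_y`.
#' @export
compare_pls_models <- function(a, b, lv = 1L) {
  if (nrow(a$saliences_x) != nrow(b$saliences_x) ||
      nrow(a$saliences_y) != nrow(b$saliences_y))
    stopf("schema error: models live on different feature spaces")
  flip <- sign(sum(a$saliences_y[, lv] * b$saliences_y[, lv]))
  if (flip == 0) flip <- 1
  list(
    salience_r_x = stats::cor(a$saliences_x[, lv], flip * b$saliences_x[, lv]),
    salience_r_y = stats::cor(a$saliences_y[, lv], flip * b$saliences_y[, lv]),
    loading_r_x = stats::cor(a$loadings_x[, lv], flip * b$loadings_x[, lv]),
    loading_r_y = stats::cor(a$loadings_y[, lv], flip * b$loadings_y[, lv])
  )
}

#' First principal component of a behaviour block
#'
#' Leading eigenvector of `Y'Y / (n - 1)`, sign-aligned against an optional
#' salience vector; used to check that the PLS behavioural salience tracks
#' the dominant behavioural variance direction.
#'
#' @param y Standardized behaviour block.
#' @param salience Optional vector to correlate against (sign-aligned).
#' @return List with `component` (unit vector) and `correlation` (NULL when
#'   no salience is supplied).
#' @export
first_principal_component <- function(y, salience = NULL) {
  y <- as.matrix(y)
  pc <- svd(y, nu = 0, nv = 1)$v[, 1]
  corr <- NULL
  if (!is.null(salience)) {
    if (length(salience) != length(pc))
      stopf("schema error: salience length does not match")
    corr <- stats::cor(pc, salience)
    if (!is.na(corr) && corr < 0) {
      pc <- -pc
      corr <- -corr
    }
  }
  list(component = pc, correlation = corr)
}
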