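# Connectome-based prediction and classification. The harness (nested CV,
# repeats, label permutations, metrics, leakage guards) is the contract; the
# learners are compact in-package kernel machines — an L2 (squared-hinge)
# SVM and a squared epsilon-insensitive SVR — solved by BFGS with analytic
# gradients, since no quadratic-programming SVM solver is available in the
# supported dependency set. Both are standard large-margin formulations with
# the same C/gamma semantics as the usual solvers.

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# squared epsilon-insensitive SVR, primal weight space (used when the linear
# kernel is requested and p <= n): min 0.5||w||^2 + C sum max(0,|r|-eps)^2
svr_fit_linear <- function(x, y, cost, epsilon = 0.1) {
  p <- ncol(x)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    r <- y - drop(x %*% w) - b
    ex <- pmax(abs(r) - epsilon, 0)
    0.5 * sum(w^2) + cost * sum(ex^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    r <- y - drop(x %*% w) - b
    ex <- pmax(abs(r) - epsilon, 0)
    g <- -2 * cost * sign(r) * ex
    c(w + drop(crossprod(x, g)), sum(g))
  }
  fit <- stats::optim(numeric(p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1], epsilon = epsilon,
       predict = function(newx) drop(newx %*% fit$par[seq_len(p)]) + fit$par[p + 1])
}

# L2-SVM (squared hinge) in the kernel dual representation:
# min 0.5 beta'K beta + C sum max(0, 1 - y f)^2, f = K beta + b
svm_fit_kernel <- function(k, y, cost) {
  n <- nrow(k)
  obj <- function(par) {
    beta <- par[seq_len(n)]; b <- par[n + 1]
    f <- drop(k %*% beta) + b
    m <- pmax(1 - y * f, 0)
    0.5 * sum(beta * drop(k %*% beta)) + cost * sum(m^2)
  }
  grad <- function(par) {
    beta <- par[seq_len(n)]; b <- par[n + 1]
    kb <- drop(k %*% beta)
    m <- pmax(1 - y * (kb + b), 0)
    g <- -2 * cost * y * m
    c(kb + drop(k %*% g), sum(g))
  }
  fit <- stats::optim(numeric(n + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  list(beta = fit$par[seq_len(n)], b = fit$par[n + 1])
}

fold_assignment <- function(n, folds, seed, stream, index) {
  with_seed(child_seed(seed, stream, index), sample(rep_len(seq_len(folds), n)))
}

stratified_folds <- function(labels, folds, seed, stream, index) {
  out <- integer(length(labels))
  with_seed(child_seed(seed, stream, index), {
    for (g in unique(labels)) {
      idx <- which(labels == g)
      out[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  out
}

# train-fold feature scaler (fit on train, applied to test)
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sds <- pmax(col_sds(x), 1e-12)
  list(mu = mu, sds = sds)
}
apply_scaler <- function(s, x) scale_cols(x, s$mu, s$sds)

# one full repeated-outer-CV SVR pipeline; returns mean prediction per subject
svr_pipeline <- function(x, y, c_grid, outer_folds, inner_folds, repetitions,
                         seed, stream_base = 0L, epsilon = 0.1) {
  n <- nrow(x)
  pred_sum <- numeric(n)
  for (rep_i in seq_len(repetitions)) {
    fa <- fold_assignment(n, outer_folds, seed, "svr", stream_base + rep_i)
    for (f in seq_len(outer_folds)) {
      test <- fa == f
      xtr <- x[!test, , drop = FALSE]; ytr <- y[!test]
      sc <- fit_scaler(xtr)
      xtr <- apply_scaler(sc, xtr)
      best_c <- c_grid[1]
      if (length(c_grid) > 1) {
        ifa <- fold_assignment(nrow(xtr), inner_folds, seed, "svr",
                               100000L + stream_base + rep_i * 100L + f)
        perf <- vapply(c_grid, function(cc) {
          preds <- numeric(nrow(xtr))
          for (g in seq_len(inner_folds)) {
            iv <- ifa == g
            fitg <- svr_fit_linear(xtr[!iv, , drop = FALSE], ytr[!iv], cc,
                                   epsilon)
            preds[iv] <- fitg$predict(xtr[iv, , drop = FALSE])
          }
          suppressWarnings(stats::cor(preds, ytr))
        }, numeric(1))
        perf[is.na(perf)] <- -Inf
        best_c <- c_grid[which.max(perf)]
      }
      fit <- svr_fit_linear(xtr, ytr, best_c, epsilon)
      pred_sum[test] <- pred_sum[test] +
        fit$predict(apply_scaler(sc, x[test, , drop = FALSE]))
    }
  }
  pred_sum / repetitions
}

#' Connectome-based prediction of a continuous target (SVR, nested CV)
#'
#' Nested cross-validation: the inner loop selects the cost parameter C from
#' the grid by held-out Pearson r, the outer loop produces held-out
#' predictions for every subject; the whole pipeline is repeated and
#' per-subject predictions averaged. Significance comes from shuffling the
#' target and rerunning the pipeline. Feature scaling is fitted on outer
#' training folds only.
#'
#' @param x Subjects x E edge matrix (raw features).
#' @param y Continuous target (e.g. a sleep-quality score).
#' @param mask Logical E-vector of features to use (e.g. the significant
#'   connectome from an independent discovery cohort), or NULL for
#'   whole-brain. An externally fixed mask may be applied globally; a
#'   data-derived mask must be derived upstream of this call on independent
#'   data.
#' @param c_grid Cost grid (default `seq(0.1, 1, by = 0.1)`).
#' @param outer_folds,inner_folds CV folds (default 10/10).
#' @param repetitions Pipeline repetitions averaged per subject (default 100).
#' @param n_perm Target permutations for the p-value (default 1000; each
#'   permutation reruns the pipeline once).
#' @param seed RNG seed.
#' @param epsilon SVR insensitivity width (default 0.1).
#' @return A `prediction_report`: `predictions` (per-subject means),
#'   `r`, `mae`, `baseline_mae` (mean absolute deviation of y, the
#'   constant-predictor reference), `permuted_p`, settings.
#' @export
svr_predict_cv <- function(x, y, mask = NULL, c_grid = seq(0.1, 1, by = 0.1),
                           outer_folds = 10, inner_folds = 10,
                           repetitions = 100, n_perm = 1000, seed = 1L,
                           epsilon = 0.1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (stats::sd(y) < 1e-12) stopf("invalid target: y is constant")
  if (!is.null(mask)) {
    if (length(mask) != ncol(x)) stopf("mask length must equal feature count")
    if (!any(mask)) stopf("mask selects no features")
    x <- x[, mask, drop = FALSE]
  }
  pred <- svr_pipeline(x, y, c_grid, outer_folds, inner_folds, repetitions,
                       seed, 0L, epsilon)
  r <- stats::cor(pred, y)
  mae <- mean(abs(pred - y))
  permuted_p <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      yp <- with_seed(child_seed(seed, "svrperm", b), sample(y))
      pp <- svr_pipeline(x, yp, c_grid, outer_folds, inner_folds, 1L,
                         seed, 200000L + b * 7L, epsilon)
      if (stats::cor(pp, yp) >= r) exceed <- exceed + 1L
    }
    permuted_p <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(predictions = pred, r = r, mae = mae,
                 baseline_mae = mean(abs(y - mean(y))),
                 permuted_p = permuted_p,
                 mask_mode = if (is.null(mask)) "whole-brain" else "masked",
                 n_features = ncol(x), c_grid = c_grid,
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 repetitions = repetitions, n_perm = n_perm,
                 epsilon = epsilon, seed = seed),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %s (%d features): r = %.3f, MAE = %.3f (baseline %.3f), permuted p = %s\n",
              x$mask_mode, x$n_features, x$r, x$mae, x$baseline_mae,
              format(signif(x$permuted_p, 3))))
  invisible(x)
}

# one repeated-CV RBF-SVM pipeline; returns per-repetition metrics and the
# per-subject decision-value sums
svm_pipeline <- function(x, labels, c_grid, gamma_grid, outer_folds,
                         inner_folds, repetitions, seed, stream_base = 0L) {
  n <- nrow(x)
  y <- ifelse(labels == 1L, 1, -1)
  acc <- sens <- spec <- numeric(repetitions)
  dec_sum <- numeric(n)
  grid <- expand.grid(C = c_grid, gamma = gamma_grid)
  for (rep_i in seq_len(repetitions)) {
    fa <- stratified_folds(labels, outer_folds, seed, "svm",
                           stream_base + rep_i)
    dec <- numeric(n)
    for (f in seq_len(outer_folds)) {
      test <- fa == f
      xtr <- x[!test, , drop = FALSE]; ytr <- y[!test]
      sc <- fit_scaler(xtr)
      xtr <- apply_scaler(sc, xtr)
      xte <- apply_scaler(sc, x[test, , drop = FALSE])
      best <- grid[1, ]
      if (nrow(grid) > 1) {
        ifa <- stratified_folds(labels[!test], inner_folds, seed, "svm",
                                100000L + stream_base + rep_i * 100L + f)
        perf <- vapply(seq_len(nrow(grid)), function(gi) {
          km <- rbf_kernel(xtr, xtr, grid$gamma[gi])
          correct <- 0L
          for (g in seq_len(inner_folds)) {
            iv <- ifa == g
            fitg <- svm_fit_kernel(km[!iv, !iv, drop = FALSE], ytr[!iv],
                                   grid$C[gi])
            fg <- drop(km[iv, !iv, drop = FALSE] %*% fitg$beta) + fitg$b
            correct <- correct + sum(sign(fg) == ytr[iv])
          }
          correct
        }, numeric(1))
        best <- grid[which.max(perf), ]
      }
      km <- rbf_kernel(xtr, xtr, best$gamma)
      fit <- svm_fit_kernel(km, ytr, best$C)
      dec[test] <- drop(rbf_kernel(xte, xtr, best$gamma) %*% fit$beta) + fit$b
    }
    pred <- ifelse(dec >= 0, 1L, 0L)
    acc[rep_i] <- mean(pred == labels)
    sens[rep_i] <- mean(pred[labels == 1L] == 1L)
    spec[rep_i] <- mean(pred[labels == 0L] == 0L)
    dec_sum <- dec_sum + dec
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       mean_decision = dec_sum / repetitions)
}

#' Area under the ROC curve from decision values
#'
#' Rank-based (Mann-Whitney) AUC; ties contribute 1/2.
#' @param decision Decision values or scores.
#' @param labels Binary labels (1 = positive class).
#' @export
auc_score <- function(decision, labels) {
  pos <- decision[labels == 1L]
  neg <- decision[labels != 1L]
  if (!length(pos) || !length(neg)) stopf("need both classes for AUC")
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

#' Two-group classification with an RBF-kernel SVM (nested CV)
#'
#' Stratified outer folds; an inner stratified grid search over (C, gamma)
#' per outer training set; accuracy/sensitivity/specificity from pooled
#' outer-test predictions per repetition, averaged over repetitions; AUC
#' from per-subject mean decision values; significance by label permutation.
#' A `meaningful` flag marks mean accuracy above 70%.
#'
#' @param x Subjects x E edge matrix.
#' @param labels Binary labels (0/1; 1 = patient class).
#' @param mask Logical feature mask (see [svr_predict_cv()]), or NULL.
#' @param c_grid Cost grid (default `2^seq(-5, 15, by = 2)`).
#' @param gamma_grid RBF width grid (default `2^seq(-15, 3, by = 2)`).
#' @param outer_folds,inner_folds CV folds (default 10/10).
#' @param repetitions Pipeline repetitions (default 100).
#' @param n_perm Label permutations (default 1000; one pipeline run each).
#' @param seed RNG seed.
#' @return A `classification_report`: mean `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `mean_decision` per subject, `permuted_p`,
#'   `meaningful`, settings.
#' @export
svm_classify_cv <- function(x, labels, mask = NULL,
                            c_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            outer_folds = 10, inner_folds = 10,
                            repetitions = 100, n_perm = 1000, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2L || !all(labels %in% c(0L, 1L)))
    stopf("invalid target: labels must contain both classes, coded 0/1")
  if (min(table(labels)) < 5) stopf("each class needs at least 5 subjects")
  if (!is.null(mask)) {
    if (length(mask) != ncol(x)) stopf("mask length must equal feature count")
    if (!any(mask)) stopf("mask selects no features")
    x <- x[, mask, drop = FALSE]
  }
  obs <- svm_pipeline(x, labels, c_grid, gamma_grid, outer_folds,
                      inner_folds, repetitions, seed)
  accuracy <- mean(obs$accuracy)
  permuted_p <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      lp <- with_seed(child_seed(seed, "svmperm", b), sample(labels))
      pp <- svm_pipeline(x, lp, c_grid, gamma_grid, outer_folds,
                         inner_folds, 1L, seed, 300000L + b * 11L)
      if (mean(pp$accuracy) >= accuracy) exceed <- exceed + 1L
    }
    permuted_p <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(accuracy = accuracy,
                 sensitivity = mean(obs$sensitivity),
                 specificity = mean(obs$specificity),
                 auc = auc_score(obs$mean_decision, labels),
                 mean_decision = obs$mean_decision,
                 permuted_p = permuted_p,
                 meaningful = accuracy > 0.70,
                 mask_mode = if (is.null(mask)) "whole-brain" else "masked",
                 n_features = ncol(x), c_grid = c_grid,
                 gamma_grid = gamma_grid, outer_folds = outer_folds,
                 inner_folds = inner_folds, repetitions = repetitions,
                 n_perm = n_perm, seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> %s (%d features): accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f, permuted p = %s\n",
    x$mask_mode, x$n_features, 100 * x$accuracy, 100 * x$sensitivity,
    100 * x$specificity, x$auc, format(signif(x$permuted_p, 3))))
  invisible(x)
}

#' Side-by-side comparison of masked vs whole-brain reports
#'
#' Descriptive only (no hypothesis test): metric pairs and their differences
#' for two reports produced on identical subjects, targets and seeds.
#'
#' @param report_masked,report_wholebrain Two reports of the same class.
#' @return Data frame with one row per metric.
#' @export
compare_feature_sets <- function(report_masked, report_wholebrain) {
  if (!identical(class(report_masked), class(report_wholebrain)))
    stopf("invalid comparison: reports are of different types")
  if (!identical(report_masked$seed, report_wholebrain$seed) ||
      !identical(report_masked$repetitions, report_wholebrain$repetitions))
    stopf("invalid comparison: reports use different seeds or settings")
  metrics <- if (inherits(report_masked, "prediction_report")) {
    c("r", "mae")
  } else {
    c("accuracy", "sensitivity", "specificity", "auc")
  }
  data.frame(
    metric = metrics,
    masked = vapply(metrics, function(m) report_masked[[m]], numeric(1)),
    whole_brain = vapply(metrics, function(m) report_wholebrain[[m]], numeric(1)),
    difference = vapply(metrics, function(m)
      report_masked[[m]] - report_wholebrain[[m]], numeric(1)),
    row.names = NULL
  )
}
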