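# Confound residualization and standardization with strict train/test
# separation: all parameters (OLS slopes, residual means and sds) come from
# the training subjects and are merely applied to held-out subjects, which is
# what keeps cross-validated composite correlations leakage-free.

#' Fit a per-column confound residualizer
#'
#' Ordinary least squares of every data column on `[1 | confounds]`; the
#' training residuals' mean and sd are stored so held-out data can be
#' standardized with training parameters only.
#'
#' @param data Subjects x M numeric matrix.
#' @param confounds Subjects x Q numeric matrix (categoricals numerically
#'   coded), or NULL for pure centering/scaling.
#' @return A `residualizer` with `coefficients` ((Q+1) x M), `column_means`,
#'   `column_sds`, `constant` flags and `fitted_on`.
#' @export
fit_residualizer <- function(data, confounds = NULL) {
  data <- as.matrix(data)
  n <- nrow(data)
  q <- if (is.null(confounds)) 0L else ncol(as.matrix(confounds))
  if (n <= q + 1) stopf("need more subjects (%d) than confounds + 1 (%d)", n, q + 1)
  design <- cbind(`(Intercept)` = rep(1, n), if (q > 0) as.matrix(confounds))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    bad <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    stopf("collinearity error: confound column(s) %s are linearly dependent",
          paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qrd, data)
  resid <- data - design %*% coef
  sds <- col_sds(resid)
  constant <- sds < 1e-12
  sds[constant] <- 1 # flagged columns pass through as zeros
  structure(list(
    coefficients = coef,
    column_means = colMeans(resid),
    column_sds = sds,
    constant = constant,
    n_confounds = q,
    fitted_on = n
  ), class = "residualizer")
}

#' @export
print.residualizer <- function(x, ...) {
  cat(sprintf("<residualizer> %d columns, %d confounds, fitted on %d subjects\n",
              ncol(x$coefficients), x$n_confounds, x$fitted_on))
  invisible(x)
}

#' Apply a fitted residualizer to (new) data
#'
#' `out = (data - [1|confounds] B - mu) / sigma` using only stored training
#' parameters.
#'
#' @param model A `residualizer` from [fit_residualizer()].
#' @param data Subjects x M matrix with the same columns as at fit time.
#' @param confounds Subjects x Q matrix matching the fit.
#' @param standardize Divide by training sds (default TRUE); FALSE leaves
#'   centred residuals for diagnostic runs.
#' @export
apply_residualizer <- function(model, data, confounds = NULL,
                               standardize = TRUE) {
  data <- as.matrix(data)
  if (ncol(data) != ncol(model$coefficients))
    stopf("schema error: %d data columns but residualizer fitted on %d",
          ncol(data), ncol(model$coefficients))
  q <- if (is.null(confounds)) 0L else ncol(as.matrix(confounds))
  if (q != model$n_confounds)
    stopf("schema error: %d confound columns but residualizer fitted with %d",
          q, model$n_confounds)
  design <- cbind(rep(1, nrow(data)), if (q > 0) as.matrix(confounds))
  resid <- data - design %*% model$coefficients
  out <- sweep(resid, 2L, model$column_means, "-")
  if (standardize) out <- sweep(out, 2L, model$column_sds, "/")
  if (any(model$constant)) out[, model$constant] <- 0
  out
}

#' Serialize / restore a residualizer (JSON)
#' @param model A `residualizer`.
#' @param path JSON path.
#' @export
write_residualizer <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_residualizer
#' @export
read_residualizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- as.matrix(x$coefficients)
  structure(x, class = "residualizer")
}

#' Map each column to standard-normal quantiles by rank
#'
#' Each value becomes `qnorm((rank - 0.5) / n)`, with ties receiving the mean
#' of their tied quantile positions; a monotone (Gaussianizing) transform of
#' every column. Constant columns are returned as zeros.
#'
#' @param data Subjects x M numeric matrix.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 3) stopf("need at least 3 subjects")
  apply(data, 2L, function(col) {
    if (stats::sd(col) < 1e-12) return(rep(0, n))
    stats::qnorm((rank(col, ties.method = "average") - 0.5) / n)
  })
}
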