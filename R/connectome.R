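# Subject-level functional connectivity: Pearson correlation between region
# time courses, Fisher r-to-z, and canonical vectorization of the upper
# triangle.

#' Pearson correlation matrix from a parcellated time series
#'
#' @param ts Timepoints x regions numeric matrix (mean BOLD per region).
#' @return Symmetric regions x regions correlation matrix with unit diagonal.
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stopf("need at least 3 timepoints, got %d", nrow(ts))
  if (any(!is.finite(ts))) stopf("time series must be finite")
  sds <- col_sds(ts)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stopf("degenerate signal: constant time course in region(s) %s",
          paste(bad - 1L, collapse = ", "))
  }
  r <- stats::cor(ts)
  diag(r) <- 1
  r
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r)`, applied elementwise; improves the normality of correlation
#' coefficients before group-level analysis.
#'
#' @param r Correlations in (-1, 1).
#' @param clip If TRUE, values at |r| = 1 are clipped to 1 - 1e-7 instead of
#'   erroring. Perfect correlations usually signal duplicated regions, so the
#'   default is a hard error.
#' @return z scores, same shape as `r`.
#' @export
fisher_z <- function(r, clip = FALSE) {
  if (any(!is.finite(r))) stopf("correlations must be finite")
  if (any(abs(r) >= 1)) {
    if (!clip) stopf("|r| >= 1 encountered; enable clip=TRUE or fix the input")
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  atanh(r)
}

#' Vectorize a symmetric matrix into canonical edge order
#'
#' Returns the strict upper triangle row-major — (0,1), (0,2), ...,
#' (0,n-1), (1,2), ... — matching [edge_index()].
#'
#' @param m Square symmetric matrix.
#' @param tol Maximum allowed asymmetry.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
vectorize_fc <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stopf("matrix must be square")
  if (max(abs(m - t(m))) > tol)
    stopf("matrix asymmetric beyond tolerance %g", tol)
  # column-major lower triangle of a symmetric matrix == row-major upper
  m[lower.tri(m)]
}

#' Inverse of [vectorize_fc()]
#'
#' @param v Edge vector of length `n (n - 1) / 2`.
#' @param n_regions Number of regions.
#' @param diag_value Diagonal fill (1 for correlation matrices).
#' @export
devectorize_fc <- function(v, n_regions, diag_value = 1) {
  if (length(v) != count_edges(n_regions))
    stopf("edge vector length %d does not match count_edges(%d) = %d",
          length(v), n_regions, count_edges(n_regions))
  m <- matrix(0, n_regions, n_regions)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Build a stacked edge matrix from per-subject time-series files
#'
#' Each file is a TSV whose columns are regions and rows are timepoints; the
#' pipeline computes the Pearson FC matrix, Fisher-z transforms it, and
#' vectorizes it into the canonical edge order.
#'
#' @param paths Named character vector of TSV paths (names become subject
#'   ids; basenames are used otherwise).
#' @param n_regions Expected parcellation size (checked against each file).
#' @param clip Passed to [fisher_z()].
#' @return An [edge_matrix()].
#' @export
build_fc <- function(paths, n_regions = NULL, clip = FALSE) {
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(paths))
  rows <- lapply(paths, function(p) {
    ts <- as.matrix(utils::read.delim(p, check.names = FALSE))
    if (!is.null(n_regions) && ncol(ts) != n_regions)
      stopf("%s has %d regions, expected %d", p, ncol(ts), n_regions)
    vectorize_fc(fisher_z(offdiag_guard(compute_fc(ts)), clip = clip),
                 tol = 1e-6)
  })
  n <- if (is.null(n_regions)) {
    (1 + sqrt(1 + 8 * length(rows[[1]]))) / 2
  } else n_regions
  edge_matrix(do.call(rbind, rows), n, ids)
}

# atanh(1) on the diagonal is infinite; zero the diagonal before the
# transform so only off-diagonal entries are checked/transformed
offdiag_guard <- function(m) {
  diag(m) <- 0
  m
}
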