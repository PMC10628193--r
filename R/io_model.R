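# Data model: region metadata, edge matrices, behaviour tables, and the
# canonical edge indexing every other module relies on.

#' Number of unique edges for a parcellation
#'
#' A symmetric connectivity matrix over `n_regions` regions has
#' `n (n - 1) / 2` unique off-diagonal edges; for the 246-region parcellation
#' used throughout, that is 30,135.
#'
#' @param n_regions Number of regions (positive integer).
#' @return Integer edge count.
#' @export
#' @examples
#' count_edges(246) # 30135
count_edges <- function(n_regions) {
  if (!is_count(n_regions) || n_regions < 1)
    stopf("`n_regions` must be a positive integer, got %s", format(n_regions))
  as.integer(n_regions * (n_regions - 1) / 2)
}

#' Canonical edge index for a region pair
#'
#' Edges are ordered row-major along the strict upper triangle with 0-based
#' region ids: (0,1), (0,2), ..., (0,n-1), (1,2), .... One fixed convention
#' keeps saved loading vectors portable across runs and tools.
#'
#' @param i,j 0-based region ids with `i < j`.
#' @param n_regions Number of regions.
#' @return 0-based edge position in `0 .. count_edges(n_regions) - 1`.
#' @export
edge_index <- function(i, j, n_regions) {
  if (!is_count(n_regions) || n_regions < 2)
    stopf("`n_regions` must be an integer >= 2")
  if (any(!is.finite(i)) || any(!is.finite(j)))
    stopf("region ids must be finite")
  if (any(i != floor(i)) || any(j != floor(j)))
    stopf("region ids must be integers")
  if (any(i < 0) || any(j >= n_regions))
    stopf("region ids out of range [0, %d)", n_regions)
  if (any(i >= j))
    stopf("edge_index requires i < j (strict upper triangle)")
  as.integer(i * n_regions - i * (i + 1) / 2 + (j - i - 1))
}

#' Inverse of [edge_index()]: recover the region pair of an edge
#'
#' @param k 0-based edge position.
#' @param n_regions Number of regions.
#' @return Integer vector `c(i, j)` (0-based) for scalar `k`, or a 2-column
#'   matrix for vector `k`.
#' @export
edge_pair <- function(k, n_regions) {
  e <- count_edges(n_regions)
  if (any(k < 0) || any(k >= e)) stopf("edge position out of range [0, %d)", e)
  if (any(k != floor(k))) stopf("edge positions must be integers")
  # row i holds (n - 1 - i) edges; invert the cumulative count
  k <- as.double(k)
  n <- as.double(n_regions)
  i <- floor(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k))
  # guard against floating-point edge cases at row boundaries
  row_start <- i * n - i * (i + 1) / 2
  i <- ifelse(k < row_start, i - 1, i)
  row_start <- i * n - i * (i + 1) / 2
  j <- i + 1 + (k - row_start)
  out <- cbind(i = as.integer(i), j = as.integer(j))
  if (nrow(out) == 1L) c(out) else out
}

#' All region pairs in canonical edge order
#'
#' @param n_regions Number of regions.
#' @return E x 2 integer matrix of 0-based (i, j) pairs.
#' @export
edge_pairs <- function(n_regions) {
  e <- count_edges(n_regions)
  if (e == 0L) return(cbind(i = integer(0), j = integer(0)))
  p <- edge_pair(seq_len(e) - 1L, n_regions)
  if (is.null(dim(p))) p <- cbind(i = p[1], j = p[2])
  p
}

# ---- RegionTable -----------------------------------------------------------

#' Construct and validate a region metadata table
#'
#' @param region_id 0-based contiguous integer ids.
#' @param name Region names.
#' @param network Network label per region (e.g. the seven cortical networks
#'   plus "subcortical"); must be non-empty.
#' @param hemisphere "L", "R" or NA.
#' @param x,y,z Centroid coordinates in millimetres.
#' @return A `region_table` (data.frame subclass).
#' @export
region_table <- function(region_id, name, network, hemisphere, x, y, z) {
  df <- data.frame(
    region_id = as.integer(region_id), name = as.character(name),
    network = as.character(network),
    hemisphere = as.character(hemisphere),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  validate_region_table(df)
}

validate_region_table <- function(df) {
  need <- c("region_id", "name", "network", "hemisphere", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("region table schema error: missing column(s) %s",
          paste(miss, collapse = ", "))
  if (anyDuplicated(df$region_id))
    stopf("region table schema error: duplicate region_id")
  n <- nrow(df)
  if (!identical(sort(as.integer(df$region_id)), 0:(n - 1L)))
    stopf("region_id must be 0-based and contiguous (0..N-1)")
  if (any(!nzchar(df$network)) || anyNA(df$network))
    stopf("network labels must be non-empty")
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stopf("region centroids must be finite")
  bad <- !df$hemisphere %in% c("L", "R") & !is.na(df$hemisphere)
  if (any(bad)) stopf("hemisphere must be L, R or NA")
  df <- df[order(df$region_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_table", "data.frame")
  df
}

#' Read / write a region table (TSV with header)
#' @param path File path.
#' @return A `region_table`.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_region_table(df)
}

#' @rdname read_region_table
#' @param regions A `region_table`.
#' @export
write_region_table <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Region centroid matrix (N x 3, millimetres)
#' @param regions A `region_table`.
#' @export
region_centroids <- function(regions) {
  as.matrix(as.data.frame(regions)[, c("x", "y", "z")])
}

# ---- EdgeMatrix ------------------------------------------------------------

#' Construct a subjects x edges connectivity block
#'
#' Rows are subjects (Fisher-z edge weights in canonical edge order), with
#' `n_regions` recording the parcellation the edges came from.
#'
#' @param values Numeric subjects x E matrix.
#' @param n_regions Number of regions (E must equal `count_edges(n_regions)`).
#' @param subject_ids Unique subject identifiers, one per row.
#' @return An `edge_matrix`.
#' @export
edge_matrix <- function(values, n_regions, subject_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub-%04d", seq_len(nrow(values)))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stopf("subject_ids must be unique")
  if (length(subject_ids) != nrow(values))
    stopf("one subject id per row required")
  if (ncol(values) != count_edges(n_regions))
    stopf("edge matrix has %d columns but count_edges(%d) = %d",
          ncol(values), n_regions, count_edges(n_regions))
  if (any(!is.finite(values))) stopf("edge values must be finite")
  dimnames(values) <- list(subject_ids, NULL)
  structure(list(values = values, n_regions = as.integer(n_regions),
                 subject_ids = subject_ids),
            class = "edge_matrix")
}

#' @export
print.edge_matrix <- function(x, ...) {
  cat(sprintf("<edge_matrix> %d subjects x %d edges (%d regions)\n",
              nrow(x$values), ncol(x$values), x$n_regions))
  invisible(x)
}

#' Read / write an edge matrix (TSV; first column `subject_id`)
#' @param path File path.
#' @param n_regions Parcellation size; inferred from the column count when
#'   omitted.
#' @export
read_edge_matrix <- function(path, n_regions = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df))
    stopf("edge matrix schema error: missing `subject_id` column")
  vals <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  storage.mode(vals) <- "double"
  if (is.null(n_regions)) {
    e <- ncol(vals)
    n_regions <- (1 + sqrt(1 + 8 * e)) / 2
    if (n_regions != floor(n_regions))
      stopf("column count %d is not a valid edge count n(n-1)/2", e)
  }
  edge_matrix(vals, n_regions, df$subject_id)
}

#' @rdname read_edge_matrix
#' @param edges An `edge_matrix`.
#' @export
write_edge_matrix <- function(edges, path) {
  df <- data.frame(subject_id = edges$subject_ids,
                   edges$values, check.names = FALSE)
  names(df) <- c("subject_id", sprintf("e%05d", seq_len(ncol(edges$values)) - 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- BehaviorTable ---------------------------------------------------------

#' Construct a subjects x measures behaviour block with confounds
#'
#' @param values Numeric subjects x P matrix of behavioural measures (P >= 2).
#' @param confounds Numeric subjects x Q matrix (categoricals numerically
#'   coded by the caller), or NULL for none.
#' @param subject_ids Unique subject identifiers.
#' @param measure_names,confound_names Column names.
#' @param impute Policy for missing measure values: reject (default) or
#'   impute column means with a warning.
#' @return A `behavior_table`.
#' @export
behavior_table <- function(values, confounds = NULL,
                           subject_ids = rownames(values),
                           measure_names = colnames(values),
                           confound_names = colnames(confounds),
                           impute = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2) stopf("behaviour table needs at least 2 measures")
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub-%04d", seq_len(nrow(values)))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stopf("subject_ids must be unique")
  if (is.null(measure_names)) measure_names <- sprintf("m%02d", seq_len(ncol(values)))
  if (anyNA(values)) {
    if (!impute) stopf("missing behavioural values; set impute=TRUE to use column means")
    warning("imputing missing behavioural values with column means", call. = FALSE)
    for (jj in seq_len(ncol(values))) {
      nas <- is.na(values[, jj])
      if (any(nas)) values[nas, jj] <- mean(values[, jj], na.rm = TRUE)
    }
  }
  if (any(!is.finite(values))) stopf("behavioural values must be finite")
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    storage.mode(confounds) <- "double"
    if (nrow(confounds) != nrow(values))
      stopf("confound rows must match behaviour rows")
    if (any(!is.finite(confounds))) stopf("confound values must be finite")
    if (is.null(confound_names))
      confound_names <- sprintf("c%02d", seq_len(ncol(confounds)))
    dimnames(confounds) <- list(subject_ids, confound_names)
  } else {
    confound_names <- character(0)
  }
  dimnames(values) <- list(subject_ids, measure_names)
  structure(list(values = values, confounds = confounds,
                 subject_ids = subject_ids,
                 measure_names = as.character(measure_names),
                 confound_names = as.character(confound_names)),
            class = "behavior_table")
}

#' @export
print.behavior_table <- function(x, ...) {
  cat(sprintf("<behavior_table> %d subjects x %d measures (+%d confounds)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$confounds)) 0L else ncol(x$confounds)))
  invisible(x)
}

#' Read / write a behaviour table (TSV; `subject_id` + measure columns)
#'
#' @param path Measures TSV path.
#' @param confound_path Optional confounds TSV (same format).
#' @export
read_behavior_table <- function(path, confound_path = NULL) {
  read_block <- function(p) {
    if (!file.exists(p)) stopf("file not found: %s", p)
    df <- utils::read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"subject_id" %in% names(df))
      stopf("behaviour table schema error: missing `subject_id` column")
    vals <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- df$subject_id
    vals
  }
  vals <- read_block(path)
  conf <- NULL
  if (!is.null(confound_path)) {
    conf <- read_block(confound_path)
    if (!identical(rownames(conf), rownames(vals)))
      stopf("alignment error: confound subject ids differ from behaviour subject ids")
  }
  behavior_table(vals, conf, rownames(vals))
}

#' @rdname read_behavior_table
#' @param behavior A `behavior_table`.
#' @export
write_behavior_table <- function(behavior, path, confound_path = NULL) {
  df <- data.frame(subject_id = behavior$subject_ids, behavior$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(confound_path) && !is.null(behavior$confounds)) {
    dfc <- data.frame(subject_id = behavior$subject_ids, behavior$confounds,
                      check.names = FALSE)
    utils::write.table(dfc, confound_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a square connectivity matrix (whitespace-delimited, no header)
#'
#' Auto-vectorizes the N x N symmetric matrix into canonical edge order.
#' @param path Text file with N rows of N whitespace-separated values.
#' @param tol Symmetry tolerance passed to [vectorize_fc()].
#' @return List with `values` (edge vector) and `n_regions`.
#' @export
read_fc_matrix <- function(path, tol = 1e-8) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    stopf("expected a square matrix, got %d x %d", nrow(m), ncol(m))
  list(values = vectorize_fc(m, tol = tol), n_regions = nrow(m))
}

#' Check that two blocks cover the same subjects in the same order
#'
#' Alignment is by subject id, never by row position alone.
#' @param edges An `edge_matrix`.
#' @param behavior A `behavior_table`.
#' @export
check_alignment <- function(edges, behavior) {
  a <- edges$subject_ids
  b <- behavior$subject_ids
  if (length(a) != length(b) || !setequal(a, b))
    stopf("alignment error: subject sets differ between edge and behaviour blocks (%d vs %d subjects, %d shared)",
          length(a), length(b), length(intersect(a, b)))
  if (!identical(a, b))
    stopf("alignment error: subject order differs between blocks; reorder by id first")
  invisible(TRUE)
}

#' Write an analysis artifact to JSON
#'
#' Drops heavyweight matrices (saliences/scores are kept), so the result is a
#' reviewable provenance record.
#' @param artifact A list or model object.
#' @param path Output JSON path.
#' @export
write_result <- function(artifact, path) {
  x <- unclass(artifact)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read back a JSON artifact written by [write_result()]
#' @param path JSON path.
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
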