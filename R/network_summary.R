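# Summaries of the significant edge pattern: FDR thresholding of edge
# loadings, count/percentage reports, network block averages over the seven
# cortical networks (+ subcortical), and signed region-importance (weighted
# degree) scores.

#' Per-edge p-values for loading correlations
#'
#' Default mode: two-sided p of the Pearson loading (correlation between each
#' edge and the edge composite score) across subjects. Alternative mode:
#' two-sided normal p of the bootstrap z ratio.
#'
#' @param model A `pls_model`.
#' @param lv LV index (default 1).
#' @param method "loading" (default) or "bootstrap_z".
#' @param boot A `bootstrap_result` (required for "bootstrap_z").
#' @return List with `loading` and `p_value` (length E).
#' @export
edge_pvalues <- function(model, lv = 1L, method = c("loading", "bootstrap_z"),
                         boot = NULL) {
  method <- match.arg(method)
  loading <- model$loadings_x[, lv]
  if (method == "loading") {
    n <- model$n_subjects
    r <- pmin(pmax(loading, -1 + 1e-15), 1 - 1e-15)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    if (is.null(boot)) stopf("bootstrap_z mode needs a bootstrap_result")
    z <- boot$bootstrap_z_x[, lv]
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(loading = loading, p_value = p)
}

#' FDR-threshold edge loadings into a significance map
#'
#' Benjamini-Hochberg across all E edges at level `q_threshold`.
#'
#' @param loading E-vector of edge loadings.
#' @param p_value E-vector of per-edge p-values.
#' @param q_threshold FDR level (default 0.05).
#' @return An `edge_significance_map` with `loading`, `p_value`, `q_value`,
#'   `mask` (logical) and `sign` (+1/-1/0).
#' @export
threshold_edges <- function(loading, p_value, q_threshold = 0.05) {
  if (length(loading) != length(p_value))
    stopf("loading and p_value must have equal length")
  if (any(p_value < 0 | p_value > 1 | !is.finite(p_value)))
    stopf("invalid input: p-values outside [0, 1]")
  q <- stats::p.adjust(p_value, method = "BH")
  mask <- q <= q_threshold
  structure(list(
    loading = loading, p_value = p_value, q_value = q, mask = mask,
    sign = ifelse(mask, sign(loading), 0),
    q_threshold = q_threshold
  ), class = "edge_significance_map")
}

#' Counts and percentages of significant edges
#'
#' Percentages use `100 * count / n_total`, rounded half-up to two decimals
#' for parity with printed reports.
#'
#' @param map An `edge_significance_map`.
#' @param n_total_edges Denominator (defaults to the map's length).
#' @return List: `n_sig`, `n_pos`, `n_neg`, `pct_sig`, `pct_pos`, `pct_neg`.
#' @export
summarize_mask <- function(map, n_total_edges = length(map$loading)) {
  n_pos <- sum(map$sign > 0)
  n_neg <- sum(map$sign < 0)
  n_sig <- n_pos + n_neg
  pct <- function(k) round_half_up(100 * k / n_total_edges, 2L)
  list(n_sig = n_sig, n_pos = n_pos, n_neg = n_neg,
       pct_sig = pct(n_sig), pct_pos = pct(n_pos), pct_neg = pct(n_neg))
}

#' Average edge values within and between networks
#'
#' Block (A, B) is the mean of `edge_values` over edges with one endpoint in
#' network A and the other in B (within-network when A = B). Empty blocks are
#' NA, not 0.
#'
#' @param edge_values E-vector (masked or raw edge loadings).
#' @param regions A [region_table()]; its network labels define the blocks.
#' @param mask Optional logical E-vector restricting the average to
#'   significant edges.
#' @return Symmetric networks x networks matrix.
#' @export
network_block_average <- function(edge_values, regions, mask = NULL) {
  n <- nrow(regions)
  if (length(edge_values) != count_edges(n))
    stopf("edge vector length %d does not match the %d-region table",
          length(edge_values), n)
  nets <- sort(unique(regions$network))
  pairs <- edge_pairs(n)
  ni <- regions$network[match(pairs[, 1], regions$region_id)]
  nj <- regions$network[match(pairs[, 2], regions$region_id)]
  if (anyNA(ni) || anyNA(nj)) stopf("schema error: unknown network label")
  keep <- if (is.null(mask)) rep(TRUE, length(edge_values)) else mask
  out <- matrix(NA_real_, length(nets), length(nets),
                dimnames = list(nets, nets))
  for (a in seq_along(nets)) {
    for (b in a:length(nets)) {
      sel <- keep & ((ni == nets[a] & nj == nets[b]) |
                       (ni == nets[b] & nj == nets[a]))
      if (any(sel)) out[a, b] <- out[b, a] <- mean(edge_values[sel])
    }
  }
  out
}

#' Signed region-importance (weighted degree) scores
#'
#' Every significant edge contributes its |loading| to both endpoint regions,
#' into `positive_score` or `negative_score` by the edge's sign; `degree_pos`
#' / `degree_neg` count the incident significant edges.
#'
#' @param map An `edge_significance_map`.
#' @param n_regions Parcellation size.
#' @return A `region_importance` with the four N-vectors.
#' @export
region_importance <- function(map, n_regions) {
  e <- count_edges(n_regions)
  if (length(map$loading) != e)
    stopf("map has %d edges but count_edges(%d) = %d",
          length(map$loading), n_regions, e)
  pairs <- edge_pairs(n_regions)
  pos <- neg <- numeric(n_regions)
  dpos <- dneg <- integer(n_regions)
  sel_p <- which(map$sign > 0)
  sel_n <- which(map$sign < 0)
  add <- function(acc, idx, w) {
    acc + vapply(seq_len(n_regions) - 1L, function(r)
      sum(w[idx[, 1] == r | idx[, 2] == r]), numeric(1))
  }
  if (length(sel_p)) {
    ip <- pairs[sel_p, , drop = FALSE]
    wp <- abs(map$loading[sel_p])
    pos <- add(pos, ip, wp)
    dpos <- as.integer(add(dpos, ip, rep(1, length(sel_p))))
  }
  if (length(sel_n)) {
    ineg <- pairs[sel_n, , drop = FALSE]
    wn <- abs(map$loading[sel_n])
    neg <- add(neg, ineg, wn)
    dneg <- as.integer(add(dneg, ineg, rep(1, length(sel_n))))
  }
  structure(list(positive_score = pos, negative_score = neg,
                 degree_pos = dpos, degree_neg = dneg),
            class = "region_importance")
}

#' Top-k regions by importance
#'
#' Descending by the chosen score; ties broken by region id ascending.
#'
#' @param importance A `region_importance`.
#' @param k Number of regions (default 5).
#' @param side "positive" or "negative" network.
#' @param weighted Rank by summed |loading| (default) or by edge count.
#' @return Data frame with 0-based `region_id`, `score` and `degree`.
#' @export
top_nodes <- function(importance, k = 5L,
                      side = c("positive", "negative"), weighted = TRUE) {
  side <- match.arg(side)
  score <- if (side == "positive") importance$positive_score else importance$negative_score
  degree <- if (side == "positive") importance$degree_pos else importance$degree_neg
  n <- length(score)
  if (k > n) stopf("k exceeds the number of regions")
  key <- if (weighted) score else degree
  ord <- order(-key, seq_len(n) - 1L)
  sel <- ord[seq_len(k)]
  data.frame(region_id = sel - 1L, score = score[sel], degree = degree[sel])
}
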