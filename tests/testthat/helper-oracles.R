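# Independent oracles, kept free of the implementation paths they check.

# Grid-search maximum of u' R v over unit spheres: for a fixed direction on
# one side the optimum on the other side is closed-form (R v / ||R v||), so
# the maximum is max ||R v|| scanned over a dense spherical grid on the
# smaller block (with a refinement pass in 4 dimensions).
grid_search_max <- function(r) {
  if (nrow(r) <= ncol(r)) r <- t(r) # scan the smaller side
  p <- ncol(r)
  norms <- function(v_mat) sqrt(colSums((r %*% v_mat)^2))
  angles_to_v <- function(g) {
    # hyperspherical parameterization, one column per grid point
    if (p == 2) rbind(cos(g[, 1]), sin(g[, 1]))
    else if (p == 3) rbind(cos(g[, 1]), sin(g[, 1]) * cos(g[, 2]),
                           sin(g[, 1]) * sin(g[, 2]))
    else rbind(cos(g[, 1]),
               sin(g[, 1]) * cos(g[, 2]),
               sin(g[, 1]) * sin(g[, 2]) * cos(g[, 3]),
               sin(g[, 1]) * sin(g[, 2]) * sin(g[, 3]))
  }
  angle_grid <- function(step_deg, centre_angles = NULL, window_deg = NULL) {
    step <- step_deg * pi / 180
    axes <- lapply(seq_len(p - 1), function(a) {
      full <- if (a == p - 1) c(0, 2 * pi) else c(0, pi)
      if (is.null(centre_angles)) seq(full[1], full[2], by = step)
      else seq(centre_angles[a] - window_deg * pi / 180,
               centre_angles[a] + window_deg * pi / 180, by = step)
    })
    as.matrix(expand.grid(axes))
  }
  if (p == 2) {
    max(norms(angles_to_v(angle_grid(0.05))))
  } else if (p == 3) {
    max(norms(angles_to_v(angle_grid(0.5))))
  } else {
    coarse <- angle_grid(4)
    vals <- norms(angles_to_v(coarse))
    centre <- coarse[which.max(vals), ]
    fine <- angle_grid(0.25, centre_angles = centre, window_deg = 6)
    max(vals, norms(angles_to_v(fine)))
  }
}

# Benjamini-Hochberg by hand (step-up), returning the rejection set
bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= (seq_len(m) / m) * q)
  keep <- logical(m)
  if (length(below)) keep[o[seq_len(max(below))]] <- TRUE
  keep
}

# binned variogram over all region pairs
binned_variogram <- function(values, coords, n_bins = 10, max_q = 0.7) {
  d <- as.matrix(dist(coords))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  dvec <- d[ut]
  keep <- dvec <= quantile(dvec, max_q)
  ii <- ut[keep, 1]; jj <- ut[keep, 2]; dk <- dvec[keep]
  qs <- quantile(dk, seq(0, 1, length.out = n_bins + 1))
  bin <- pmin(pmax(findInterval(dk, qs, rightmost.closed = TRUE), 1), n_bins)
  sq <- 0.5 * (values[ii] - values[jj])^2
  vapply(seq_len(n_bins), function(b) mean(sq[bin == b]), numeric(1))
}
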