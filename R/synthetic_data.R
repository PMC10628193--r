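# Synthetic cohorts with known ground truth. The stated world mirrors the
# discovery cohort: 687 subjects, a 246-region parcellation, 36 behavioural
# measures, a single shared latent dimension whose composite correlation is
# 0.5, loading on ~20% of edges and ~75% of measures, contaminated by four
# confounds (two continuous, two binary).

YEO_NETWORKS <- c("visual", "somatomotor", "dorsal_attention",
                  "ventral_attention", "limbic", "frontoparietal",
                  "default_mode")

#' Synthetic region metadata table
#'
#' Regions get centroids uniform in a brain-sized bounding box (mm),
#' hemisphere from the sign of x, and network labels cycling through the
#' seven cortical networks plus a subcortical set (~15% of regions, matching
#' 36/246).
#'
#' @param n_regions Number of regions.
#' @param seed RNG seed.
#' @return A [region_table()].
#' @export
synthetic_regions <- function(n_regions = 246, seed = 1L) {
  if (!is_count(n_regions) || n_regions < 2) stopf("need at least 2 regions")
  with_seed(child_seed(seed, "regions"), {
    n_sub <- max(1L, round(n_regions * 36 / 246))
    networks <- c(sample(rep_len(YEO_NETWORKS, n_regions - n_sub)),
                  rep("subcortical", n_sub))
    x <- stats::runif(n_regions, -70, 70)
    region_table(
      region_id = 0:(n_regions - 1L),
      name = sprintf("R%03d", 0:(n_regions - 1L)),
      network = networks,
      hemisphere = ifelse(x < 0, "L", "R"),
      x = x,
      y = stats::runif(n_regions, -100, 70),
      z = stats::runif(n_regions, -45, 80)
    )
  })
}

# unit vector supported on a random fraction of coordinates
planted_salience <- function(p, support_fraction) {
  k <- max(1L, round(p * support_fraction))
  idx <- sample.int(p, k)
  v <- numeric(p)
  v[idx] <- stats::rnorm(k)
  v / sqrt(sum(v^2))
}

# random unit directions orthogonal to `u` (one per confound), so confound
# contamination never leaks into the planted latent axis and the
# latent-strength calibration stays exact in expectation
orthogonal_directions <- function(u, q) {
  p <- length(u)
  d <- matrix(stats::rnorm(p * q), p, q)
  d <- d - outer(u, colSums(d * u)) # remove component along u
  sweep(d, 2L, sqrt(colSums(d^2)), "/")
}

#' Generate a cohort with one planted brain-behaviour latent dimension
#'
#' Each subject draws a latent score `z ~ N(0,1)`; the edge block is
#' `X = a z u' + C G_x' + noise` and the behaviour block
#' `Y = b z v' + C G_y' + noise`, with `u`, `v` unit vectors supported on a
#' configurable fraction of features and `a = b = noise_sd *
#' sqrt(rho / (1 - rho))` so that `corr(X u, Y v) = rho = latent_strength`
#' in expectation. Confound effect directions are orthogonal to `u` and `v`,
#' so contamination inflates spurious covariance without biasing the
#' calibration.
#'
#' @param n_subjects Cohort size (>= 10).
#' @param n_regions Parcellation size; edges E = n(n-1)/2.
#' @param n_behav Number of behavioural measures.
#' @param latent_strength Target correlation between the two true latent
#'   scores, in [0, 1).
#' @param support_fraction_x,support_fraction_y Fraction of edges / measures
#'   carrying the latent signal.
#' @param confound_effects Length-4 effect sizes for the default confounds
#'   (age, sex, handedness, mean FD stand-ins: two continuous, two binary).
#' @param noise_sd Gaussian noise sd per cell.
#' @param seed RNG seed; same seed gives a bit-identical cohort.
#' @return A `synthetic_cohort`: `edges` ([edge_matrix()]), `behavior`
#'   ([behavior_table()]), `true_salience_x`, `true_salience_y`,
#'   `latent_scores`, `latent_strength`, `seed`.
#' @export
generate_cohort <- function(n_subjects = 687, n_regions = 246, n_behav = 36,
                            latent_strength = 0.5,
                            support_fraction_x = 0.2,
                            support_fraction_y = 0.75,
                            confound_effects = c(0.3, 0.3, 0.2, 0.2),
                            noise_sd = 1, seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 10)
    stopf("need at least 10 subjects")
  if (!is_count(n_regions) || n_regions < 3) stopf("need at least 3 regions")
  if (!is_count(n_behav) || n_behav < 2) stopf("need at least 2 measures")
  if (!is.finite(latent_strength) || latent_strength < 0 || latent_strength >= 1)
    stopf("latent_strength must lie in [0, 1)")
  if (support_fraction_x <= 0 || support_fraction_x > 1 ||
      support_fraction_y <= 0 || support_fraction_y > 1)
    stopf("support fractions must lie in (0, 1]")
  if (!is.finite(noise_sd) || noise_sd <= 0) stopf("noise_sd must be positive")

  e <- count_edges(n_regions)
  q <- length(confound_effects)
  with_seed(child_seed(seed, "cohort"), {
    u <- planted_salience(e, support_fraction_x)
    v <- planted_salience(n_behav, support_fraction_y)
    z <- stats::rnorm(n_subjects)
    # two continuous + binary confounds mirroring age/FD and sex/handedness
    conf <- cbind(
      age = stats::rnorm(n_subjects),
      fd = stats::rnorm(n_subjects),
      sex = stats::rbinom(n_subjects, 1, 0.5),
      hand = stats::rbinom(n_subjects, 1, 0.1)
    )[, seq_len(max(q, 1L)), drop = FALSE]
    a <- noise_sd * sqrt(latent_strength / (1 - latent_strength))
    gx <- orthogonal_directions(u, max(q, 1L))
    gy <- orthogonal_directions(v, max(q, 1L))
    ce <- if (q > 0) confound_effects else 0
    x <- tcrossprod(a * z, u) +
      (conf %*% (t(gx) * ce)) +
      matrix(stats::rnorm(n_subjects * e, sd = noise_sd), n_subjects, e)
    y <- tcrossprod(a * z, v) +
      (conf %*% (t(gy) * ce)) +
      matrix(stats::rnorm(n_subjects * n_behav, sd = noise_sd),
             n_subjects, n_behav)
    ids <- sprintf("sub-%04d", seq_len(n_subjects))
    structure(list(
      edges = edge_matrix(x, n_regions, ids),
      behavior = behavior_table(y, if (q > 0) conf else NULL, ids,
                                measure_names = sprintf("sh%02d", seq_len(n_behav))),
      true_salience_x = u,
      true_salience_y = v,
      latent_scores = z,
      latent_strength = latent_strength,
      confound_effects = confound_effects,
      noise_sd = noise_sd,
      seed = seed
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d edges, %d measures, latent strength %.2f (seed %s)\n",
    nrow(x$edges$values), ncol(x$edges$values), ncol(x$behavior$values),
    x$latent_strength, format(x$seed)))
  invisible(x)
}

#' Spatially autocorrelated annotation map over region centroids
#'
#' Draws from a Gaussian process with squared-exponential kernel
#' `exp(-d^2 / (2 l^2))` over centroid distances and standardizes to zero
#' mean, unit variance — a stand-in for receptor-density maps averaged into
#' the parcellation.
#'
#' @param regions A [region_table()] (>= 3 regions).
#' @param correlation_length Kernel length scale, millimetres.
#' @param seed RNG seed.
#' @param name Map label.
#' @return An `annotation_map`: `values` (length N, standardized), `name`,
#'   `correlation_length`, `seed`.
#' @export
generate_annotation_map <- function(regions, correlation_length = 20,
                                    seed = 1L, name = "synthetic_map") {
  if (nrow(regions) < 3) stopf("need at least 3 regions")
  if (!is.finite(correlation_length) || correlation_length <= 0)
    stopf("correlation_length must be positive")
  d <- as.matrix(stats::dist(region_centroids(regions)))
  k <- exp(-d^2 / (2 * correlation_length^2))
  cf <- chol(k + diag(1e-8, nrow(k)))
  with_seed(child_seed(seed, "annotation"), {
    vals <- unname(drop(crossprod(cf, stats::rnorm(nrow(k)))))
    vals <- (vals - mean(vals)) / stats::sd(vals)
    structure(list(values = vals, name = name,
                   correlation_length = correlation_length, seed = seed),
              class = "annotation_map")
  })
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> '%s', %d regions, length scale %.1f mm\n",
              x$name, length(x$values), x$correlation_length))
  invisible(x)
}

#' Two-group cohort shifted along the planted latent dimension
#'
#' Group 1 subjects get latent scores shifted by `group_shift` relative to
#' group 0 (patients vs controls stand-in; sized after the 52/49 clinical
#' template by default).
#'
#' @param n_per_group Length-2 group sizes (>= 5 each).
#' @param group_shift Latent-score shift for group 1.
#' @param n_regions,support_fraction_x,noise_sd As in [generate_cohort()].
#' @param latent_sd Within-group latent-score spread (default 1, i.e.
#'   heterogeneous groups); small values give near-separable groups along
#'   the planted direction.
#' @param seed RNG seed.
#' @return List with `edges` ([edge_matrix()]), `labels` (0/1 integer
#'   vector), `true_salience_x`, `latent_scores`, `group_shift`, `seed`.
#' @export
generate_two_group_cohort <- function(n_per_group = c(52, 49),
                                      group_shift = 1,
                                      n_regions = 246,
                                      support_fraction_x = 0.2,
                                      noise_sd = 1, latent_sd = 1,
                                      seed = 1L) {
  n_per_group <- rep_len(n_per_group, 2L)
  if (any(n_per_group < 5)) stopf("need at least 5 subjects per group")
  if (!is_count(n_regions) || n_regions < 3) stopf("need at least 3 regions")
  e <- count_edges(n_regions)
  n <- sum(n_per_group)
  with_seed(child_seed(seed, "twogroup"), {
    u <- planted_salience(e, support_fraction_x)
    labels <- rep(c(0L, 1L), n_per_group)
    z <- stats::rnorm(n, sd = latent_sd) + group_shift * labels
    x <- tcrossprod(z, u) +
      matrix(stats::rnorm(n * e, sd = noise_sd), n, e)
    ids <- sprintf("sub-%04d", seq_len(n))
    list(edges = edge_matrix(x, n_regions, ids),
         labels = labels,
         true_salience_x = u,
         latent_scores = z,
         group_shift = group_shift,
         seed = seed)
  })
}
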