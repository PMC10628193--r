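# Shared fixtures, built in code at test time.

random_symmetric <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

tiny_regions <- function(n = 6, networks = c("default_mode", "somatomotor"),
                         seed = 1) {
  set.seed(seed)
  region_table(
    region_id = 0:(n - 1), name = sprintf("R%02d", 0:(n - 1)),
    network = rep_len(networks, n),
    hemisphere = rep_len(c("L", "R"), n),
    x = runif(n, -60, 60), y = runif(n, -80, 60), z = runif(n, -40, 70)
  )
}

# residualize both blocks of a synthetic cohort with its own confounds
residualized_blocks <- function(cohort) {
  conf <- cohort$behavior$confounds
  rx <- fit_residualizer(cohort$edges$values, conf)
  ry <- fit_residualizer(cohort$behavior$values, conf)
  list(x = apply_residualizer(rx, cohort$edges$values, conf),
       y = apply_residualizer(ry, cohort$behavior$values, conf))
}
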