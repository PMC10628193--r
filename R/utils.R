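# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a child seed from a master seed
#'
#' Deterministic, collision-avoiding stream split: each (seed, stream, index)
#' triple maps to a distinct 31-bit integer, so permutations, bootstraps and
#' CV repetitions draw from independent reproducible streams.
#' @noRd
child_seed <- function(seed, stream, index = 0L) {
  if (is.null(seed)) return(NULL)
  # small multiplicative hash, kept below 2^31 - 1
  h <- (as.double(seed) * 48271 + match(stream, c(
    "cohort", "annotation", "twogroup", "perm", "boot", "cv", "cvperm",
    "surrogate", "project", "svr", "svm", "svrperm", "svmperm", "fold",
    "regions", "other"
  ), nomatch = 16L) * 7919 + as.double(index) * 104729) %% 2147483629
  as.integer(h) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

#' Round half away from zero (report parity with printed percentages)
#' @noRd
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Column standardization with constant-column guard
#' @noRd
scale_cols <- function(x, center, sds) {
  sweep(sweep(x, 2L, center, "-"), 2L, sds, "/")
}

col_sds <- function(x) {
  apply(x, 2L, stats::sd)
}
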