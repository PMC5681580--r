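## Shared fixtures, generated in code and cached per test file.
options(borealrings.verbose = FALSE)

## Small default-structure cohort for fast structural tests.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(synth_config(
        seed = 101, n_trees = c(black_spruce = 30L, white_spruce = 30L)))
    cache
  }
})

## Deterministic flat-truth config: no climate forcing, no habitat effects.
flat_config <- function(seed = 11, n = 60L, sigma = 0.05, ...) {
  synth_config(seed = seed,
               n_trees = c(black_spruce = n, white_spruce = 0L),
               forcing = list(t_floor = 1, p_floor = 1,
                              t_prev_weight = 0, p_prev_weight = 0),
               noise_sigma = sigma, missing_pith_frac = 0, ...)
}

## A ring_set of n series with prescribed mean widths (constant series).
constant_series_set <- function(means, len = 60L, first_year = 1950L) {
  ring_set(lapply(seq_along(means), function(i)
    ring_series(sprintf("S%03d", i), first_year, rep(means[i], len),
                pith_present = TRUE)))
}

## Independent reimplementation of the biweight mean used as the oracle:
## straight iteration of the weight formula, written against the formulas,
## not the package code.
biweight_oracle <- function(x, c = 9, tol = 1e-9, iter = 50) {
  if (length(x) == 1) return(x)
  if (length(x) <= 3) return(stats::median(x))
  t <- stats::median(x)
  S <- stats::median(abs(x - stats::median(x)))
  if (S == 0) return(stats::median(x))
  for (k in seq_len(iter)) {
    u <- (x - t) / (c * S)
    keep <- abs(u) < 1
    w <- ifelse(keep, ((1 - u^2))^2, 0)
    t_new <- sum(w[keep] * x[keep]) / sum(w[keep])
    if (abs(t_new - t) < tol) break
    t <- t_new
  }
  t_new
}

## Exact circumcircle radius through three points (least-squares circle fit
## degenerates to the exact circle for three points): oracle for the
## geometric missing-radius method.
circle_fit_radius <- function(p1, p2, p3) {
  a <- sqrt(sum((p1 - p2)^2))
  b <- sqrt(sum((p2 - p3)^2))
  cc <- sqrt(sum((p3 - p1)^2))
  s <- (a + b + cc) / 2
  K <- sqrt(s * (s - a) * (s - b) * (s - cc))
  a * b * cc / (4 * K)
}
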