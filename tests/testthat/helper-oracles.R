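# Shared fixtures: random bivariate series and the exhaustive-enumeration
# oracle used against the dynamic programme.

make_series <- function(lrr, imbaf, lrr_obs = TRUE, imbaf_obs = TRUE) {
  tibble::tibble(
    lrr = lrr, imbaf = imbaf,
    lrr_observed = rep(lrr_obs, length.out = length(lrr)),
    imbaf_observed = rep(imbaf_obs, length.out = length(lrr)))
}

# Random imputed series with per-variable missingness up to `miss`.
random_series <- function(n, miss = 0.3) {
  lrr_obs <- runif(n) > miss * runif(1)
  imb_obs <- runif(n) > miss * runif(1)
  if (!any(lrr_obs)) lrr_obs[sample.int(n, 1)] <- TRUE
  if (!any(imb_obs)) imb_obs[sample.int(n, 1)] <- TRUE
  s <- make_series(rnorm(n), 0.5 + abs(rnorm(n, 0, 0.2)), lrr_obs, imb_obs)
  s$lrr[!s$lrr_observed] <- NA
  s$imbaf[!s$imbaf_observed] <- NA
  impute_constant(s)
}

# Minimum cost over all tilings into S segments, by exhaustive enumeration.
# Per-segment energies come from segment_stats() + segment_delta(), the
# single-segment path, independent of the DP's prefix-sum machinery.
brute_force_min_cost <- function(series, S, p = 0.25, beta = 1) {
  n <- nrow(series)
  if (S == 1)
    return(segment_delta(segment_stats(series, 0, n), p, beta))
  D <- matrix(NA_real_, n, n + 1)
  for (a in 0:(n - 1)) for (b in (a + 1):n)
    D[a + 1, b + 1] <- segment_delta(segment_stats(series, a, b), p, beta)
  splits <- utils::combn(n - 1, S - 1)
  best <- Inf
  for (j in seq_len(ncol(splits))) {
    t <- c(0, splits[, j], n)
    cost <- sum(D[cbind(t[-length(t)] + 1, t[-1] + 1)])
    if (cost < best) best <- cost
  }
  best
}

# Interior change-points of a segment table returned by segment_profile().
predicted_cps <- function(segments) segments$start[segments$start > 0]
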