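#' BIC-penalised Gaussian log-likelihood of a segmentation
#'
#' Scores a candidate segmentation from its optimal total cost `delta`
#' (the minimised sum of segment energies), the number of observations `N`
#' and the number of segments `S`:
#' \deqn{\log \tilde L = -\frac{N}{2}\left(1 + \log \frac{2\pi\delta}{N}\right)
#'   - k\,S\,\log N}
#' `k = 1` gives the plain BIC penalty; larger `k` selects fewer segments,
#' smaller `k` more. A zero cost (perfect fit) is floored at
#' `N * .Machine$double.eps` so the criterion stays finite while perfect fits
#' still dominate through the penalty term alone.
#'
#' @param total_cost Optimal cost `delta` of the segmentation, `>= 0`.
#' @param n_obs Number of observations `N` (observed values across both
#'   variables), `>= 2`.
#' @param n_segments Number of segments `S`, `>= 1`.
#' @param penalty_k Penalty multiplier `k > 0` (or 0 to disable the penalty).
#' @return The penalised log-likelihood (vectorised over its arguments).
#' @export
bic_loglik <- function(total_cost, n_obs, n_segments, penalty_k = 1) {
  if (any(n_obs < 2)) abort("`n_obs` must be >= 2")
  if (any(n_segments < 1)) abort("`n_segments` must be >= 1")
  if (any(total_cost < 0)) abort("`total_cost` must be >= 0")
  delta <- pmax(total_cost, n_obs * .Machine$double.eps)
  -n_obs / 2 * (1 + log(2 * pi * delta / n_obs)) -
    penalty_k * n_segments * log(n_obs)
}

#' Select the number of segments by BIC
#'
#' Picks, among the candidate segmentations of an [segment_bivariate()] fit,
#' the one maximising the BIC-penalised log-likelihood. Ties are broken
#' toward fewer segments.
#'
#' @param fit An `scm_fit` object.
#' @param penalty_k Penalty multiplier `k`; default 1 (BIC). Raising it
#'   never increases the selected number of segments.
#' @details The observation count `N` entering the criterion is the number
#'   of probes of the series: the piecewise-constant model treats each probe
#'   as one bivariate observation, and partially observed probes already
#'   weigh less in the cost through the observed-count weights.
#' @return An object of class `scm_model`: the selected candidate, a list
#'   with `changepoints`, `segments` (tibble), `deltas`, `total_cost`,
#'   `n_segments`, `loglik`, `penalty_k`, `n_obs` and the fit parameters.
#' @export
select_segments <- function(fit, penalty_k = 1) {
  if (!inherits(fit, "scm_fit")) abort("`fit` must be an `scm_fit` object")
  if (!length(fit$results)) abort("fit holds no candidate segmentations")
  costs <- vapply(fit$results, `[[`, 0, "total_cost")
  ns <- vapply(fit$results, `[[`, 1L, "n_segments")
  # N counts the bivariate observations z_k, i.e. the probes of the series:
  # the model is piecewise-constant in k = 1..n, and the missing-value
  # weighting already folds partial observation into the cost itself.
  ll <- bic_loglik(costs, fit$n, ns, penalty_k)
  best <- which(ll == max(ll))[1]  # candidates are ordered by S: ties -> smaller S
  res <- fit$results[[best]]
  segments <- tiling_stats(fit$series, res$changepoints)
  deltas <- segment_delta(segments, p = fit$params$p, beta = fit$params$beta)
  structure(
    c(res, list(segments = segments, deltas = deltas,
                loglik = ll[best], penalty_k = penalty_k, n_obs = fit$n,
                params = fit$params, scores = tibble::tibble(
                  n_segments = ns, total_cost = costs, loglik = ll))),
    class = "scm_model")
}

#' Interior change-points of a selected segmentation
#'
#' Drops the trivial boundaries `t = 0` and `t = n`, which every segmentation
#' carries by construction, leaving the change-points that scoring compares.
#'
#' @param model An `scm_model` (or `scm_fit` result entry, or a raw
#'   change-point vector including the 0/n boundaries).
#' @return Integer vector of interior change-point indices.
#' @export
interior_changepoints <- function(model) {
  t <- if (is.numeric(model)) as.integer(model) else model$changepoints
  t[-c(1, length(t))]
}

#' @export
print.scm_model <- function(x, ...) {
  cat(sprintf(
    "Selected segmentation: S = %d segments, cost = %.6g, logLik = %.6g (k = %g)\n",
    x$n_segments, x$total_cost, x$loglik, x$penalty_k))
  invisible(x)
}
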