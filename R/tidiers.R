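#' Tidy a bivariate SCM fit
#'
#' Returns one row per segment per candidate number of segments.
#'
#' @param x An `scm_fit`.
#' @param ... Unused.
#' @return Tibble with `n_segments`, `segment`, `start`, `end`, `mean_lrr`,
#'   `mean_imbaf`, `rss_lrr`, `rss_imbaf`, `n_lrr`, `n_imbaf`, `delta`.
#' @export
tidy.scm_fit <- function(x, ...) {
  purrr::map_dfr(x$results, function(r) {
    seg <- tiling_stats(x$series, r$changepoints)
    deltas <- segment_delta(seg, p = x$params$p, beta = x$params$beta)
    dplyr::mutate(seg, n_segments = r$n_segments,
                  segment = dplyr::row_number(), delta = deltas,
                  .before = 1)
  })
}

#' Glance at a bivariate SCM fit
#'
#' One row per candidate number of segments, with the optimal cost and the
#' default-penalty (BIC, `k = 1`) log-likelihood.
#'
#' @param x An `scm_fit`.
#' @param ... Unused.
#' @export
glance.scm_fit <- function(x, ...) {
  costs <- vapply(x$results, `[[`, 0, "total_cost")
  ns <- vapply(x$results, `[[`, 1L, "n_segments")
  tibble::tibble(n_segments = ns, total_cost = costs,
                 loglik = bic_loglik(costs, x$n, ns, 1),
                 n_obs = x$n_obs, n = x$n)
}

#' Tidy a selected segmentation
#'
#' @param x An `scm_model` from [select_segments()].
#' @param ... Unused.
#' @return Tibble with one row per segment.
#' @export
tidy.scm_model <- function(x, ...) {
  dplyr::mutate(x$segments, segment = dplyr::row_number(), delta = x$deltas,
                .before = 1)
}

#' Glance at a selected segmentation
#'
#' @param x An `scm_model`.
#' @param ... Unused.
#' @export
glance.scm_model <- function(x, ...) {
  tibble::tibble(n_segments = x$n_segments, total_cost = x$total_cost,
                 loglik = x$loglik, penalty_k = x$penalty_k, n_obs = x$n_obs)
}
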