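check_series <- function(series, need_complete = FALSE) {
  required <- c("lrr", "imbaf", "lrr_observed", "imbaf_observed")
  missing_cols <- setdiff(required, names(series))
  if (length(missing_cols))
    abort(paste0("series lacks column(s): ", paste(missing_cols, collapse = ", ")))
  if (nrow(series) == 0) abort("empty series")
  if (need_complete && (anyNA(series$lrr) || anyNA(series$imbaf)))
    abort("series contains missing values; run `impute_constant()` first")
  invisible(series)
}

rss_obs <- function(x, obs) {
  x <- x[obs]
  n <- length(x)
  if (n == 0) return(c(mean = NA_real_, rss = 0, n = 0))
  m <- mean(x)
  c(mean = m, rss = sum((x - m)^2), n = n)
}

#' Per-segment means and residual sums of squares
#'
#' Computes, for the half-open index range `[start, end)` of a bivariate
#' series, the segment mean and residual sum of squares of each variable over
#' its observed values only, together with the observed counts that weight
#' the segment energy.
#'
#' @param series Bivariate series ([transform_imbaf()] output, imputed or not).
#' @param start,end 0-based half-open segment bounds, `0 <= start < end <= n`.
#' @return One-row tibble with columns `start`, `end`, `mean_lrr`,
#'   `mean_imbaf`, `rss_lrr`, `rss_imbaf`, `n_lrr`, `n_imbaf`.
#' @export
segment_stats <- function(series, start, end) {
  check_series(series)
  n <- nrow(series)
  if (!(start >= 0 && start < end && end <= n))
    abort("invalid segment bounds: need 0 <= start < end <= n")
  idx <- (start + 1):end
  r <- rss_obs(series$lrr[idx], series$lrr_observed[idx])
  b <- rss_obs(series$imbaf[idx], series$imbaf_observed[idx])
  tibble::tibble(
    start = as.integer(start), end = as.integer(end),
    mean_lrr = r[["mean"]], mean_imbaf = b[["mean"]],
    rss_lrr = r[["rss"]], rss_imbaf = b[["rss"]],
    n_lrr = as.integer(r[["n"]]), n_imbaf = as.integer(b[["n"]])
  )
}

#' Minkowski-combined segment energy
#'
#' Combines the per-variable residual sums of squares of a segment into one
#' energy through a weighted Minkowski distance of order `p`:
#' \deqn{\delta_s = \left(\frac{l_r}{l_r+l_b}\,\mathrm{rss}_r^p +
#'   \frac{l_b}{l_r+l_b}\,\beta\,\mathrm{rss}_b^p\right)^{1/p}}
#' where \eqn{l_r, l_b} are the observed counts. The weights make imputed
#' (unobserved) entries cost-free, and `0^p` is taken as 0 so a perfectly
#' fitted variable contributes nothing for any `p > 0`. Orders `p < 1` reward
#' segmentations that fit at least one variable very well, which is what
#' makes strong single-variable mean shifts detectable.
#'
#' @param stats One-row data frame from [segment_stats()] (or any frame with
#'   `rss_lrr`, `rss_imbaf`, `n_lrr`, `n_imbaf`); vectorised over rows.
#' @param p Minkowski order, `p > 0`. Default 1/4.
#' @param beta Weight of the imBAF term, `beta > 0`. Default 1.
#' @return Numeric vector of segment energies, one per row of `stats`.
#' @export
segment_delta <- function(stats, p = 0.25, beta = 1) {
  if (p <= 0 || beta <= 0) abort("`p` and `beta` must be positive")
  lr <- stats$n_lrr
  lb <- stats$n_imbaf
  tot <- lr + lb
  rss_r <- pmax(stats$rss_lrr, 0)
  rss_b <- pmax(stats$rss_imbaf, 0)
  inner <- ifelse(tot == 0, 0,
                  (lr / pmax(tot, 1)) * ifelse(rss_r > 0, rss_r^p, 0) +
                  (lb / pmax(tot, 1)) * beta * ifelse(rss_b > 0, rss_b^p, 0))
  ifelse(inner > 0, inner^(1 / p), 0)
}

check_changepoints <- function(changepoints, n) {
  t <- as.integer(changepoints)
  if (length(t) < 2 || t[1] != 0 || t[length(t)] != n || is.unsorted(t, strictly = TRUE))
    abort("changepoints must be strictly increasing, starting at 0 and ending at n")
  t
}

#' Per-segment statistics for a whole tiling
#'
#' Vectorised version of [segment_stats()]: computes means, residual sums of
#' squares and observed counts for every segment of an explicit tiling, via
#' prefix sums over observed values.
#'
#' @param series Bivariate series.
#' @param changepoints Integer vector `(0, t_2, ..., n)`: strictly increasing
#'   segment borders, 0-based half-open.
#' @return Tibble with one row per segment, the columns of [segment_stats()].
#' @export
tiling_stats <- function(series, changepoints) {
  check_series(series)
  t <- check_changepoints(changepoints, nrow(series))
  lo <- t[-length(t)]
  hi <- t[-1]
  one <- function(x, obs) {
    x <- ifelse(obs, x, 0)
    s <- c(0, cumsum(x))
    ss <- c(0, cumsum(x^2))
    cnt <- c(0, cumsum(as.integer(obs)))
    l <- cnt[hi + 1] - cnt[lo + 1]
    sm <- s[hi + 1] - s[lo + 1]
    sq <- ss[hi + 1] - ss[lo + 1]
    m <- ifelse(l > 0, sm / pmax(l, 1), NA_real_)
    rss <- pmax(sq - sm^2 / pmax(l, 1), 0)
    rss <- ifelse(l > 0 & rss > 1e-9 * abs(sq), rss, 0)
    list(mean = m, rss = rss, n = as.integer(l))
  }
  r <- one(series$lrr, series$lrr_observed)
  b <- one(series$imbaf, series$imbaf_observed)
  tibble::tibble(
    start = as.integer(lo), end = as.integer(hi),
    mean_lrr = r$mean, mean_imbaf = b$mean,
    rss_lrr = r$rss, rss_imbaf = b$rss,
    n_lrr = r$n, n_imbaf = b$n)
}

#' Total cost of a given segmentation
#'
#' Evaluates the cost function \eqn{G(t_1 \dots t_S) = \sum_s \delta_s} for an
#' explicit tiling of the series. This is the plain evaluator that the exact
#' dynamic programme of [segment_bivariate()] minimises, and the natural
#' brute-force oracle for it.
#'
#' @param series Imputed bivariate series.
#' @param changepoints Integer vector `(0, t_2, ..., n)`: strictly increasing
#'   segment borders, 0-based half-open.
#' @inheritParams segment_delta
#' @return The total cost (a single number).
#' @export
segmentation_cost <- function(series, changepoints, p = 0.25, beta = 1) {
  sum(segment_delta(tiling_stats(series, changepoints), p = p, beta = beta))
}

#' Segment a bivariate LRR/imBAF series by exact dynamic programming
#'
#' Fits the piecewise-constant bivariate model for every candidate number of
#' segments `S = 1..max_segments`: each fit is the exact global minimum of the
#' summed Minkowski segment energies over all tilings whose segments are at
#' most `max_segment_length` long. Restricting the segment length bounds the
#' inner loop of the dynamic programme, reducing complexity from quadratic to
#' `O(n * max_segment_length * max_segments)`.
#'
#' The returned fit holds one candidate segmentation per feasible `S`; pick
#' one with [select_segments()] (BIC) or inspect them via [tidy()]/[glance()].
#'
#' @param series Imputed bivariate series ([impute_constant()] output). The
#'   observation masks, not the imputed values, decide which entries enter
#'   the segment energies.
#' @param max_segments Upper bound on the number of segments. Default
#'   `max(1, ceiling(n / 10))`.
#' @param max_segment_length Longest allowed segment, in probes. Default
#'   `min(n, 3000)`.
#' @inheritParams segment_delta
#' @return An object of class `scm_fit`: a list with `results` (one entry per
#'   feasible `S`, each holding `changepoints`, `total_cost`, `n_segments`),
#'   the series, `n_obs` (total observed values across both variables) and
#'   the parameters. Per-segment statistics are computed on demand by
#'   [tidy()] and [select_segments()].
#' @examples
#' series <- tibble::tibble(
#'   lrr = c(rep(0, 20), rep(1, 20)), imbaf = rep(0.55, 40),
#'   lrr_observed = TRUE, imbaf_observed = TRUE
#' )
#' fit <- segment_bivariate(series, max_segments = 4)
#' glance(fit)
#' @export
segment_bivariate <- function(series, max_segments = NULL,
                              max_segment_length = NULL, p = 0.25, beta = 1) {
  check_series(series, need_complete = TRUE)
  if (p <= 0 || beta <= 0) abort("`p` and `beta` must be positive")
  n <- nrow(series)
  if (is.null(max_segments)) max_segments <- max(1L, ceiling(n / 10))
  if (is.null(max_segment_length)) max_segment_length <- min(n, 3000L)
  max_segments <- as.integer(max_segments)
  max_segment_length <- as.integer(max_segment_length)
  if (max_segments < 1 || max_segment_length < 1)
    abort("`max_segments` and `max_segment_length` must be >= 1")
  if (as.double(max_segments) * max_segment_length < n)
    abort(sprintf(
      "infeasible constraints: %d segments of <= %d probes cannot tile %d probes",
      max_segments, max_segment_length, n))

  dp <- dp_segment_cpp(series$lrr, series$imbaf,
                       series$lrr_observed, series$imbaf_observed,
                       p, beta, max_segments, max_segment_length)

  results <- purrr::compact(purrr::imap(dp$changepoints, function(t, s) {
    if (is.null(t)) return(NULL)
    list(changepoints = as.integer(t), total_cost = dp$costs[[s]],
         n_segments = s)
  }))
  if (!length(results)) abort("no feasible segmentation found")

  structure(
    list(results = results, series = series, n = n,
         n_obs = sum(series$lrr_observed) + sum(series$imbaf_observed),
         params = list(p = p, beta = beta, max_segments = max_segments,
                       max_segment_length = max_segment_length)),
    class = "scm_fit")
}

#' @export
print.scm_fit <- function(x, ...) {
  ns <- vapply(x$results, `[[`, 1L, "n_segments")
  cat(sprintf(
    "Bivariate SCM fit: %d probes, %d observed values, S in [%d, %d] (p = %g, beta = %g)\n",
    x$n, x$n_obs, min(ns), max(ns), x$params$p, x$params$beta))
  invisible(x)
}
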