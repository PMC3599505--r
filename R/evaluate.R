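#' Match predicted against true change-points within a probe window
#'
#' A true change-point is recalled if at least one prediction falls within
#' `window` probes of it; a prediction is matched if it falls within `window`
#' probes of some true change-point. Several predictions near the same true
#' change-point all count as matched, so repeated calls of the same boundary
#' do not deflate specificity.
#'
#' @param true_cps,predicted_cps Integer vectors of interior change-point
#'   indices (the trivial 0/n boundaries should not be included).
#' @param window Matching half-width in probes. Default 3.
#' @return List with `recalled` (true change-points recalled) and `matched`
#'   (predictions lying near some true change-point).
#' @export
match_changepoints <- function(true_cps, predicted_cps, window = 3) {
  if (window < 0) abort("`window` must be >= 0")
  true_cps <- sort(unique(as.integer(true_cps)))
  predicted_cps <- sort(unique(as.integer(predicted_cps)))
  if (!length(true_cps) || !length(predicted_cps))
    return(list(recalled = integer(0), matched = integer(0)))
  d <- abs(outer(true_cps, predicted_cps, "-"))
  list(recalled = true_cps[apply(d <= window, 1, any)],
       matched = predicted_cps[apply(d <= window, 2, any)])
}

#' Score a predicted change-point set against the truth
#'
#' Sensitivity is the fraction of true change-points recalled within the
#' window; specificity the fraction of distinct predictions lying within the
#' window of some true change-point; the F-measure their harmonic mean.
#' When a `detectable_cps` subset is supplied (e.g. from
#' [signal_changepoints()]), sensitivity is computed over it — boundaries the
#' signal cannot express are not counted as misses — while predictions are
#' still matched against the full truth set, so a call at a real but
#' inexpressible boundary is not a false positive.
#'
#' @inheritParams match_changepoints
#' @param detectable_cps Optional subset of `true_cps` used as the
#'   sensitivity denominator.
#' @return One-row tibble: `n_true`, `n_predicted`, `n_recalled_true`,
#'   `n_matched_predictions`, `sensitivity`, `specificity`, `f_measure`,
#'   `window`.
#' @examples
#' score_changepoints(c(50, 100), c(50, 300), window = 3)
#' @export
score_changepoints <- function(true_cps, predicted_cps, window = 3,
                               detectable_cps = NULL) {
  true_cps <- sort(unique(as.integer(true_cps)))
  predicted_cps <- sort(unique(as.integer(predicted_cps)))
  sens_base <- if (is.null(detectable_cps)) true_cps
               else sort(unique(as.integer(detectable_cps)))
  rec <- match_changepoints(sens_base, predicted_cps, window)$recalled
  mat <- match_changepoints(true_cps, predicted_cps, window)$matched
  sens <- if (length(sens_base)) length(rec) / length(sens_base) else 1
  spec <- if (length(predicted_cps)) length(mat) / length(predicted_cps) else 1
  f <- if (sens + spec > 0) 2 * sens * spec / (sens + spec) else 0
  tibble::tibble(
    n_true = length(true_cps), n_predicted = length(predicted_cps),
    n_recalled_true = length(rec), n_matched_predictions = length(mat),
    sensitivity = sens, specificity = spec, f_measure = f,
    window = as.integer(window))
}

#' Sweep the model-selection penalty into a ROC table
#'
#' Segments every sample once (the dynamic programme does not depend on the
#' penalty), then, for each penalty value, selects the number of segments,
#' scores the selected change-points against the sample's truth and averages
#' across samples. Lower penalties select more segments, trading specificity
#' for sensitivity.
#'
#' @param samples List of samples; each a list with elements `series` (an
#'   imputed bivariate series) and `true_cps` (integer vector), optionally
#'   `detectable_cps`.
#' @param penalty_grid Numeric vector of penalty multipliers `k`.
#' @param window Matching window in probes. Default 3.
#' @param ... Passed to [segment_bivariate()] (`p`, `beta`, `max_segments`,
#'   `max_segment_length`).
#' @return Tibble sorted by `penalty_k` with mean `sensitivity`,
#'   `specificity` and `f_measure` across samples.
#' @export
roc_sweep <- function(samples, penalty_grid, window = 3, ...) {
  if (!length(samples) || !length(penalty_grid))
    abort("`samples` and `penalty_grid` must be non-empty")
  fits <- purrr::map(samples, function(s) segment_bivariate(s$series, ...))
  rows <- purrr::map_dfr(sort(penalty_grid), function(k) {
    scores <- purrr::map2_dfr(fits, samples, function(fit, s) {
      model <- select_segments(fit, penalty_k = k)
      score_changepoints(s$true_cps, interior_changepoints(model),
                         window = window, detectable_cps = s$detectable_cps)
    })
    tibble::tibble(penalty_k = k,
                   sensitivity = mean(scores$sensitivity),
                   specificity = mean(scores$specificity),
                   f_measure = mean(scores$f_measure))
  })
  rows
}
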