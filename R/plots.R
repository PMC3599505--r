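#' Plot a segmented LRR/imBAF profile
#'
#' Draws the two signal tracks with the fitted per-segment means and the
#' selected change-points.
#'
#' @param series Bivariate series (imputed or not).
#' @param model Optional `scm_model` whose segments and change-points to
#'   overlay.
#' @return A ggplot object (two facets: LRR and imBAF).
#' @export
plot_profile <- function(series, model = NULL) {
  long <- dplyr::bind_rows(
    tibble::tibble(index = seq_len(nrow(series)) - 1L, value = series$lrr,
                   observed = series$lrr_observed, track = "LRR"),
    tibble::tibble(index = seq_len(nrow(series)) - 1L, value = series$imbaf,
                   observed = series$imbaf_observed, track = "imBAF"))
  long$track <- factor(long$track, levels = c("LRR", "imBAF"))
  p <- ggplot2::ggplot(long[long$observed, ],
                       ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "probe index", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    seg <- model$segments
    means <- dplyr::bind_rows(
      tibble::tibble(start = seg$start, end = seg$end, value = seg$mean_lrr,
                     track = factor("LRR", levels = c("LRR", "imBAF"))),
      tibble::tibble(start = seg$start, end = seg$end, value = seg$mean_imbaf,
                     track = factor("imBAF", levels = c("LRR", "imBAF"))))
    p <- p +
      ggplot2::geom_segment(
        data = means[!is.na(means$value), ],
        ggplot2::aes(x = .data$start, xend = .data$end - 1L,
                     y = .data$value, yend = .data$value),
        colour = "red", linewidth = 0.7) +
      ggplot2::geom_vline(xintercept = interior_changepoints(model),
                          linetype = "dashed", colour = "blue",
                          linewidth = 0.3)
  }
  p
}

#' @export
autoplot.scm_model <- function(object, series = NULL, ...) {
  if (is.null(series))
    abort("supply the `series` the model was fitted to")
  plot_profile(series, object)
}

#' Plot a penalty-sweep ROC table
#'
#' Sensitivity against specificity across the penalty grid, with F-measure
#' isocurves in grey.
#'
#' @param sweep Tibble from [roc_sweep()].
#' @return A ggplot object.
#' @export
plot_roc <- function(sweep) {
  iso <- purrr::map_dfr(seq(0.1, 0.9, by = 0.1), function(f) {
    spec <- seq(f / (2 - f) + 1e-6, 1, length.out = 100)
    tibble::tibble(f = f, specificity = spec,
                   sensitivity = f * spec / (2 * spec - f))
  })
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$specificity,
                                      y = .data$sensitivity)) +
    ggplot2::geom_line(data = iso,
                       ggplot2::aes(group = .data$f), colour = "grey80") +
    ggplot2::geom_path(colour = "red") +
    ggplot2::geom_point(ggplot2::aes(size = .data$penalty_k), colour = "red") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "specificity", y = "sensitivity", size = "penalty k") +
    ggplot2::theme_minimal()
}
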