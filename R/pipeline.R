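#' Segment a multi-chromosome probe table end to end
#'
#' Runs the whole method on a probe table, chromosome by chromosome: BAF is
#' mirrored and reduced to informative SNPs, missing values are filled by
#' constant interpolation, the bivariate structural change model is fitted by
#' exact dynamic programming, and the number of segments is chosen by the
#' BIC-penalised log-likelihood. Chromosomes are never concatenated, so no
#' spurious cross-chromosome change-points can arise.
#'
#' @param probes Probe tibble (`probe_id`, `chrom`, `position`, `lrr`,
#'   `baf`), e.g. from [read_probe_table()] or [simulate_sample()].
#' @param hom_threshold Homozygosity threshold on the mBAF scale. Default 0.95.
#' @param p,beta Minkowski order and imBAF weight; defaults 1/4 and 1.
#' @param penalty_k Model-selection penalty multiplier; default 1 (BIC).
#' @param max_segments,max_segment_length Dynamic-programming constraints,
#'   per chromosome; `NULL` uses the [segment_bivariate()] defaults.
#' @param quiet Suppress per-chromosome progress messages. Default `TRUE`.
#' @return Tibble with one row per selected segment: `chrom`, `start`, `end`
#'   (0-based half-open probe indices within the chromosome),
#'   `start_position`, `end_position` (bp of first/last probe), `n_probes`,
#'   `n_informative`, `mean_lrr`, `mean_imbaf`, `delta`. The per-chromosome
#'   `scm_model` objects are attached as the `"models"` attribute.
#' @examples
#' prof <- simulate_profile("near_diploid", lengths = c(20, 40), seed = 1)
#' probes <- simulate_sample(prof, seed = 2)
#' segs <- segment_profile(probes, max_segment_length = 200)
#' @export
segment_profile <- function(probes, hom_threshold = 0.95, p = 0.25, beta = 1,
                            penalty_k = 1, max_segments = NULL,
                            max_segment_length = NULL, quiet = TRUE) {
  if (nrow(probes) == 0) abort("empty probe table")
  chroms <- unique(probes$chrom)
  models <- list()
  failed <- character(0)
  rows <- purrr::map(chroms, function(ch) {
    t0 <- Sys.time()
    out <- tryCatch({
      track <- probes |> dplyr::filter(.data$chrom == ch)
      series <- transform_imbaf(track, hom_threshold = hom_threshold) |>
        impute_constant()
      fit <- segment_bivariate(series, max_segments = max_segments,
                               max_segment_length = max_segment_length,
                               p = p, beta = beta)
      model <- select_segments(fit, penalty_k = penalty_k)
      models[[ch]] <<- model
      if (!quiet)
        message(sprintf(
          "chrom %s: n = %d (lrr %d, imbaf %d observed), S = %d, cost = %.4g, %.2fs",
          ch, nrow(series), sum(series$lrr_observed),
          sum(series$imbaf_observed), model$n_segments, model$total_cost,
          as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      seg <- model$segments
      tibble::tibble(
        chrom = ch, start = seg$start, end = seg$end,
        start_position = series$position[seg$start + 1L],
        end_position = series$position[seg$end],
        n_probes = seg$end - seg$start,
        n_informative = seg$n_imbaf,
        mean_lrr = seg$mean_lrr, mean_imbaf = seg$mean_imbaf,
        delta = model$deltas)
    }, error = function(e) {
      failed <<- c(failed, paste0(ch, ": ", conditionMessage(e)))
      NULL
    })
    out
  })
  if (length(failed))
    abort(paste0("segmentation failed on chromosome(s):\n  ",
                 paste(failed, collapse = "\n  ")))
  out <- dplyr::bind_rows(rows)
  attr(out, "models") <- models
  out
}

#' Run the file-to-file segmentation pipeline
#'
#' Thin wrapper over [read_probe_table()], [segment_profile()] and
#' [write_segments()]: reads a probe table, segments it and writes
#' `<output_prefix>.segments.tsv` plus
#' `<output_prefix>.segments.tsv.changepoints`.
#'
#' @param input Path to a tab-delimited probe table.
#' @param output_prefix Prefix for the output files.
#' @param ... Passed to [segment_profile()].
#' @return The segment tibble, invisibly.
#' @export
run_pipeline <- function(input, output_prefix, ...) {
  probes <- read_probe_table(input)
  segments <- segment_profile(probes, ...)
  write_segments(segments, paste0(output_prefix, ".segments.tsv"))
  invisible(segments)
}
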