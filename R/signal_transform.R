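#' Mirror B allele frequencies along the 0.5 axis
#'
#' Folds raw BAF values into mirrored BAF (mBAF) on `[0.5, 1]`, removing the
#' arbitrary labelling of the A and B alleles: `mBAF = |BAF - 0.5| + 0.5`.
#' Missing values propagate.
#'
#' @param baf Numeric vector of B allele frequencies in `[0, 1]`; `NA` allowed.
#' @param probe_id Optional identifiers used in error messages.
#' @return Numeric vector of mBAF values in `[0.5, 1]`.
#' @examples
#' mirror_baf(c(0.3, 0.5, 1.0, NA))
#' @export
mirror_baf <- function(baf, probe_id = NULL) {
  bad <- !is.na(baf) & (baf < 0 | baf > 1)
  if (any(bad)) {
    who <- if (!is.null(probe_id)) paste(probe_id[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    abort(paste0("BAF values outside [0, 1] at probe(s): ", who))
  }
  abs(baf - 0.5) + 0.5
}

#' Classify informative SNPs on the mirrored-BAF scale
#'
#' A probe is informative when its mBAF is observed and lies below the
#' homozygosity threshold. Probes in the homozygous band (and probes with
#' missing BAF, e.g. non-polymorphic markers) carry no allelic information
#' and are flagged non-informative; their imBAF is treated as missing.
#'
#' @param mbaf Numeric vector of mirrored BAF values in `[0.5, 1]`; `NA` allowed.
#' @param hom_threshold mBAF at or above which a SNP is called homozygous.
#'   Must lie in `(0.5, 1]`. Default 0.95.
#' @return Logical vector, `TRUE` for informative probes.
#' @export
classify_informative <- function(mbaf, hom_threshold = 0.95) {
  if (length(hom_threshold) != 1 || is.na(hom_threshold) ||
      hom_threshold <= 0.5 || hom_threshold > 1)
    abort("`hom_threshold` must be a single value in (0.5, 1]")
  bad <- !is.na(mbaf) & (mbaf < 0.5 | mbaf > 1)
  if (any(bad)) abort("mBAF values outside [0.5, 1]; mirror BAF first")
  !is.na(mbaf) & mbaf < hom_threshold
}

#' Build the bivariate LRR/imBAF series for one chromosome
#'
#' Converts a single-chromosome probe table into the aligned bivariate series
#' that segmentation operates on: LRR is passed through, BAF is mirrored and
#' non-informative (homozygous-band or missing) probes get a missing imBAF.
#' Observation masks record, per variable, which entries were actually
#' measured; they are preserved by [impute_constant()] and drive the
#' missing-value weights of the segment energy.
#'
#' @param probes Data frame with columns `probe_id`, `chrom`, `position`,
#'   `lrr`, `baf` covering a single chromosome, sorted by position.
#' @param hom_threshold Homozygosity threshold on the mBAF scale; see
#'   [classify_informative()].
#' @return A tibble with one row per probe and columns `index` (0-based
#'   series index), `probe_id`, `chrom`, `position`, `lrr`, `imbaf`,
#'   `lrr_observed`, `imbaf_observed`.
#' @examples
#' probes <- tibble::tibble(
#'   probe_id = paste0("rs", 1:5), chrom = "1", position = 1:5 * 1000L,
#'   lrr = rnorm(5, 0, 0.1), baf = c(0.50, 0.02, 0.51, 0.98, 0.49)
#' )
#' transform_imbaf(probes)
#' @export
transform_imbaf <- function(probes, hom_threshold = 0.95) {
  required <- c("probe_id", "chrom", "position", "lrr", "baf")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols))
    abort(paste0("probe table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  if (nrow(probes) == 0) abort("empty probe track")
  if (length(unique(probes$chrom)) != 1)
    abort("`transform_imbaf()` expects a single chromosome; split by `chrom` first")
  if (is.unsorted(probes$position, strictly = TRUE))
    abort("probe positions must be strictly increasing within a chromosome")

  mbaf <- mirror_baf(probes$baf, probes$probe_id)
  informative <- classify_informative(mbaf, hom_threshold)
  tibble::tibble(
    index = seq_len(nrow(probes)) - 1L,
    probe_id = probes$probe_id,
    chrom = probes$chrom,
    position = probes$position,
    lrr = probes$lrr,
    imbaf = ifelse(informative, mbaf, NA_real_),
    lrr_observed = !is.na(probes$lrr),
    imbaf_observed = informative
  )
}

locf_fill <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0) return(x)
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  idx[idx == 0L] <- obs[1]
  x[idx]
}

#' Impute missing series values by constant interpolation
#'
#' Fills every missing LRR or imBAF value with the nearest preceding observed
#' value of the same variable (leading gaps take the first observed value).
#' Constant interpolation keeps imputed imBAF on the discrete band structure
#' of the signal, which linear interpolation would blur with values between
#' bands. Observation masks are left untouched, so imputed entries still
#' carry zero weight in the segment energy.
#'
#' @param series Bivariate series as returned by [transform_imbaf()].
#' @return The series with `lrr` and `imbaf` fully observed.
#' @export
impute_constant <- function(series) {
  if (nrow(series) == 0) abort("empty series")
  for (v in c("lrr", "imbaf")) {
    if (all(is.na(series[[v]])))
      abort(paste0(
        "no observed ", v, " values on this chromosome; ",
        "bivariate segmentation is undefined - run the other variable alone ",
        "on a series built without this one"
      ))
    series[[v]] <- locf_fill(series[[v]])
  }
  series
}
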