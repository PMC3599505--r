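#' Expected log R ratio of a tumour/normal mixture
#'
#' Under the two-population mixture model, a locus with tumour copy number
#' `c` in a sample with normal-cell fraction `w` has total copy
#' `w * 2 + (1 - w) * c`, hence an expected LRR of
#' `log2((w * 2 + (1 - w) * c) / 2)` plus the array's ploidy-dependent
#' baseline shift. Contamination shrinks the signal towards the diploid 0.
#'
#' @param copy_number Tumour copy number (integer `>= 0`); vectorised.
#' @param contamination Fraction `w` of normal cells in `[0, 1]`.
#' @param baseline_shift Additive LRR shift from array normalisation on
#'   non-diploid genomes.
#' @param floor LRR returned when the mixture copy number is 0 (homozygous
#'   deletion in a pure tumour), instead of `-Inf`. Default -5.
#' @return Expected LRR values.
#' @examples
#' expected_lrr(4)                 # log2(2) = 1
#' expected_lrr(1, contamination = 0.5)
#' @export
expected_lrr <- function(copy_number, contamination = 0, baseline_shift = 0,
                         floor = -5) {
  if (any(copy_number < 0)) abort("`copy_number` must be >= 0")
  if (any(contamination < 0 | contamination > 1))
    abort("`contamination` must lie in [0, 1]")
  mixture <- contamination * 2 + (1 - contamination) * copy_number
  out <- ifelse(mixture > 0, log2(mixture / 2) + baseline_shift, floor)
  pmax(out, floor)
}

#' Expected B allele frequency of a tumour/normal mixture
#'
#' The expected BAF is the B-allele dosage over the total dosage of the
#' mixture: `(w * n_b_normal + (1 - w) * n_b_tumour) / (w * 2 + (1 - w) *
#' copy_tumour)`. At `w = 1` it collapses to the germline `n_b_normal / 2`.
#'
#' @param n_b_tumour B-allele count in the tumour, `0..copy_tumour`.
#' @param copy_tumour Tumour copy number.
#' @param n_b_normal Germline B-allele count (0 = AA, 1 = AB, 2 = BB).
#' @param contamination Fraction `w` of normal cells in `[0, 1]`.
#' @return Expected BAF in `[0, 1]`.
#' @export
expected_baf <- function(n_b_tumour, copy_tumour, n_b_normal = 1,
                         contamination = 0) {
  if (any(n_b_tumour < 0 | n_b_tumour > copy_tumour))
    abort("`n_b_tumour` must lie in [0, copy_tumour]")
  if (any(!n_b_normal %in% 0:2)) abort("`n_b_normal` must be 0, 1 or 2")
  if (any(contamination < 0 | contamination > 1))
    abort("`contamination` must lie in [0, 1]")
  denom <- contamination * 2 + (1 - contamination) * copy_tumour
  if (any(denom == 0)) abort("mixture copy number is 0: BAF undefined")
  (contamination * n_b_normal + (1 - contamination) * n_b_tumour) / denom
}

# Alteration rosters behind the named tumour patterns. Each pattern states a
# background (copy number, B alleles) and the set of altered states laid on
# it; `rep` repeats a state once per length at every requested length.
pattern_spec <- function(pattern) {
  st <- function(cn, nb, loh, rep = 1L)
    tibble::tibble(copy_number = cn, n_b_alleles = nb, loh_type = loh, rep = rep)
  switch(pattern,
    near_diploid = list(
      background = c(cn = 2L, nb = 1L),
      states = dplyr::bind_rows(
        st(1L, 0L, "somatic"), st(2L, 0L, "somatic"), st(2L, 0L, "germline"),
        st(3L, 1L, "none"), st(3L, 0L, "somatic"), st(4L, 2L, "none"),
        st(4L, 0L, "somatic"), st(5L, 2L, "none"), st(5L, 0L, "somatic"))),
    near_triploid = list(
      background = c(cn = 3L, nb = 1L),
      states = dplyr::bind_rows(
        st(1L, 0L, "somatic"), st(2L, 1L, "none"), st(2L, 0L, "germline"),
        st(3L, 0L, "somatic"), st(4L, 2L, "none"), st(4L, 0L, "somatic"),
        st(5L, 2L, "none"), st(5L, 0L, "somatic"))),
    near_tetraploid = list(
      background = c(cn = 4L, nb = 2L),
      states = dplyr::bind_rows(
        st(1L, 0L, "somatic"), st(2L, 1L, "none"), st(2L, 0L, "somatic"),
        st(3L, 1L, "none"), st(3L, 0L, "somatic"), st(4L, 0L, "somatic"),
        st(5L, 2L, "none"), st(5L, 0L, "somatic"))),
    loh_enriched = list(
      background = c(cn = 2L, nb = 1L),
      states = dplyr::bind_rows(
        st(2L, 0L, "germline", rep = 4L), st(1L, 0L, "somatic"),
        st(2L, 0L, "somatic"), st(3L, 1L, "none"), st(3L, 0L, "somatic"),
        st(4L, 0L, "somatic"), st(5L, 0L, "somatic"))),
    complex = list(
      background = c(cn = 2L, nb = 1L),
      states = dplyr::bind_rows(
        st(1L, 0L, "somatic"), st(2L, 0L, "somatic"), st(2L, 0L, "germline"),
        st(3L, 1L, "none"), st(3L, 0L, "somatic"), st(4L, 2L, "none"),
        st(4L, 1L, "none"), st(4L, 0L, "somatic"), st(5L, 2L, "none"),
        st(5L, 1L, "none"), st(5L, 0L, "somatic"))),
    abort(paste0("unknown pattern: ", pattern))
  )
}

#' Simulate a ground-truth tumour copy-number profile
#'
#' Lays copy-number/LOH alterations on a pattern-specific background state,
#' separated by background gaps, and draws germline genotypes per probe
#' (heterozygous with probability `het_rate`, forced homozygous inside
#' germline-LOH regions). The true change-points are exactly the probe
#' indices where the `(copy_number, n_b_alleles)` state changes.
#'
#' Patterns: `near_diploid` (diploid background), `near_triploid` /
#' `near_tetraploid` (background copy 3 / 4), `loh_enriched` (diploid with
#' extra long germline-LOH stretches), `complex` (all alteration types,
#' including allelic imbalances at copy 4-5).
#'
#' @param pattern One of `"near_diploid"`, `"near_triploid"`,
#'   `"near_tetraploid"`, `"loh_enriched"`, `"complex"`.
#' @param lengths Alteration sizes in probes; every pattern state is placed
#'   once at every length. Default `c(10, 20, 40, 80, 160)`.
#' @param gap Background probes between consecutive alterations (and at the
#'   flanks). Default 30.
#' @param het_rate Probability that a probe is germline-heterozygous.
#'   Default 0.3.
#' @param states Optional tibble with columns `copy_number`, `n_b_alleles`,
#'   `loh_type` overriding the pattern's roster; an optional `cell_fraction`
#'   column in `(0, 1]` makes an alteration subclonal (only that fraction of
#'   tumour cells carries it, the rest keep the background state; default 1).
#' @param shuffle Shuffle the placement order of alterations (seeded).
#' @param seed Integer seed; the profile is reproducible given it.
#' @return A `cnv_profile` object: list with `probes` (tibble: `index`,
#'   `copy_number`, `n_b_alleles`, `loh_type`, `genotype`), `alterations`
#'   (tibble with `start_probe`, `n_probes`, state columns),
#'   `changepoints` (integer vector), `pattern`, `background`, `het_rate`.
#' @examples
#' prof <- simulate_profile("near_diploid", lengths = c(10, 40), seed = 1)
#' length(prof$changepoints)
#' @export
simulate_profile <- function(pattern = c("near_diploid", "near_triploid",
                                         "near_tetraploid", "loh_enriched",
                                         "complex"),
                             lengths = c(10L, 20L, 40L, 80L, 160L),
                             gap = 30L, het_rate = 0.3, states = NULL,
                             shuffle = TRUE, seed = NULL) {
  pattern <- match.arg(pattern)
  if (any(lengths < 1)) abort("alteration `lengths` must be >= 1")
  if (gap < 1) abort("`gap` must be >= 1 so alterations stay disjoint")
  if (het_rate <= 0 || het_rate >= 1) abort("`het_rate` must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)

  spec <- pattern_spec(pattern)
  if (is.null(states)) states <- spec$states
  if (!"rep" %in% names(states)) states$rep <- 1L
  if (!"cell_fraction" %in% names(states)) states$cell_fraction <- 1
  if (any(states$cell_fraction <= 0 | states$cell_fraction > 1))
    abort("`cell_fraction` must lie in (0, 1]")
  alts <- tidyr::crossing(
    states |> tidyr::uncount(.data$rep) |>
      dplyr::mutate(state_id = dplyr::row_number()),
    n_probes = as.integer(lengths))
  if (shuffle) alts <- alts[sample.int(nrow(alts)), ]

  bg_cn <- spec$background[["cn"]]
  bg_nb <- spec$background[["nb"]]
  pos <- gap
  starts <- integer(nrow(alts))
  for (i in seq_len(nrow(alts))) {
    starts[i] <- pos
    pos <- pos + alts$n_probes[i] + gap
  }
  alts$start_probe <- starts
  n <- pos

  cn <- rep(bg_cn, n)
  nb <- rep(bg_nb, n)
  loh <- rep("none", n)
  cf <- rep(1, n)
  for (i in seq_len(nrow(alts))) {
    idx <- alts$start_probe[i] + seq_len(alts$n_probes[i])  # 1-based rows
    cn[idx] <- alts$copy_number[i]
    nb[idx] <- alts$n_b_alleles[i]
    loh[idx] <- alts$loh_type[i]
    cf[idx] <- alts$cell_fraction[i]
  }

  genotype <- ifelse(runif(n) < het_rate, "AB",
                     ifelse(runif(n) < 0.5, "AA", "BB"))
  genotype[loh == "germline"] <- ifelse(runif(sum(loh == "germline")) < 0.5,
                                        "AA", "BB")

  state_change <- which(cn[-1] != cn[-n] | nb[-1] != nb[-n] |
                          cf[-1] != cf[-n])  # boundary index
  probes <- tibble::tibble(
    index = seq_len(n) - 1L, copy_number = cn, n_b_alleles = nb,
    loh_type = loh, genotype = genotype, cell_fraction = cf)

  structure(
    list(probes = probes,
         alterations = alts[, c("start_probe", "n_probes", "copy_number",
                                "n_b_alleles", "loh_type", "cell_fraction")],
         changepoints = as.integer(state_change),
         pattern = pattern,
         background = c(cn = bg_cn, nb = bg_nb),
         het_rate = het_rate),
    class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("CNV truth profile: pattern %s, %d probes, %d alterations, %d change-points\n",
              x$pattern, nrow(x$probes), nrow(x$alterations),
              length(x$changepoints)))
  invisible(x)
}

probe_baseline_shift <- function(profile, contamination) {
  bg <- profile$background[["cn"]]
  mix <- contamination * 2 + (1 - contamination) * bg
  -log2(mix / 2)
}

# Effective tumour state and allele counts per probe. A subclonal alteration
# (cell_fraction < 1) mixes the altered state with the profile's background
# state among the tumour cells, giving fractional effective copy numbers.
# Heterozygous probes take the region's B count, with a random allele flip
# (unphased SNPs); homozygous probes keep all copies on one allele.
probe_tumour_state <- function(profile, flip) {
  pr <- profile$probes
  cf <- if ("cell_fraction" %in% names(pr)) pr$cell_fraction else 1
  c_eff <- (1 - cf) * profile$background[["cn"]] + cf * pr$copy_number
  b_reg <- (1 - cf) * profile$background[["nb"]] + cf * pr$n_b_alleles
  flip <- rep(flip, length.out = nrow(pr))
  b_t <- ifelse(pr$genotype == "AA", 0,
         ifelse(pr$genotype == "BB", c_eff,
                ifelse(flip, c_eff - b_reg, b_reg)))
  b_n <- unname(c(AA = 0L, AB = 1L, BB = 2L)[pr$genotype])
  list(copy = c_eff, b_tumour = b_t, b_normal = b_n)
}

#' Simulate an observed SNP-array sample from a truth profile
#'
#' Realises LRR and BAF observations around the mixture-model expectations of
#' the profile's states: Gaussian noise on both signals (BAF clamped to
#' `[0, 1]`), a fraction of probes with missing BAF (non-polymorphic
#' markers), and an LRR baseline shift that recentres the sample's background
#' state at 0 (as array normalisation does). The LRR noise level is about six
#' times the BAF noise level at the defaults.
#'
#' @param profile A `cnv_profile` from [simulate_profile()].
#' @param contamination Fraction of normal cells `w` in `[0, 1]`. Default 0.
#' @param sd_lrr,sd_baf Gaussian noise standard deviations. Defaults 0.30
#'   and 0.05.
#' @param missing_baf_rate Probability a probe's BAF is missing. Default 0.05.
#' @param baseline_shift LRR shift; `NULL` (default) recentres the
#'   background state of the pattern at LRR 0.
#' @param chrom Chromosome label for the output table. Default `"1"`.
#' @param position_step Base pairs between consecutive probes. Default 1000.
#' @param seed Integer seed; the sample is reproducible given it.
#' @return Probe tibble with columns `probe_id`, `chrom`, `position`, `lrr`,
#'   `baf`, ready for [transform_imbaf()] or [write_probe_table()].
#' @examples
#' prof <- simulate_profile("near_diploid", lengths = c(20, 40), seed = 1)
#' sample <- simulate_sample(prof, contamination = 0.25, seed = 2)
#' @export
simulate_sample <- function(profile, contamination = 0, sd_lrr = 0.30,
                            sd_baf = 0.05, missing_baf_rate = 0.05,
                            baseline_shift = NULL, chrom = "1",
                            position_step = 1000L, seed = NULL) {
  if (!inherits(profile, "cnv_profile")) abort("`profile` must be a `cnv_profile`")
  if (sd_lrr < 0 || sd_baf < 0) abort("noise standard deviations must be >= 0")
  if (missing_baf_rate < 0 || missing_baf_rate >= 1)
    abort("`missing_baf_rate` must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(baseline_shift))
    baseline_shift <- probe_baseline_shift(profile, contamination)

  pr <- profile$probes
  n <- nrow(pr)
  state <- probe_tumour_state(profile, flip = runif(n) < 0.5)
  mu_lrr <- expected_lrr(state$copy, contamination, baseline_shift)
  mu_baf <- expected_baf(state$b_tumour, state$copy, state$b_normal,
                         contamination)
  lrr <- mu_lrr + rnorm(n, sd = sd_lrr)
  baf <- pmin(1, pmax(0, mu_baf + rnorm(n, sd = sd_baf)))
  baf[runif(n) < missing_baf_rate] <- NA_real_

  tibble::tibble(
    probe_id = sprintf("p%06d", pr$index),
    chrom = chrom,
    position = (pr$index + 1L) * as.integer(position_step),
    lrr = lrr, baf = baf)
}

#' Change-points actually expressed by the noiseless expected signal
#'
#' Not every true state boundary is visible to LRR/imBAF segmentation: a
#' copy-neutral germline-LOH region has no informative SNPs and no LRR shift,
#' and a copy-neutral somatic LOH in a pure tumour (`w = 0`) pushes its
#' heterozygous probes' BAF to exactly 0/1, past the homozygosity threshold.
#' This helper computes the change-points of the expected (noiseless)
#' bivariate series after the same mBAF transformation, informativity
#' classification and constant interpolation that the pipeline applies —
#' i.e. the boundaries a perfect segmenter could recover. A noiseless sample
#' segmented with BIC recovers exactly this set.
#'
#' @inheritParams simulate_sample
#' @param hom_threshold Homozygosity threshold, as in [transform_imbaf()].
#' @return Integer vector of expressed change-point indices (a subset of the
#'   positions where the expected imputed series changes).
#' @export
signal_changepoints <- function(profile, contamination = 0,
                                baseline_shift = NULL, hom_threshold = 0.95) {
  if (!inherits(profile, "cnv_profile")) abort("`profile` must be a `cnv_profile`")
  if (is.null(baseline_shift))
    baseline_shift <- probe_baseline_shift(profile, contamination)
  pr <- profile$probes
  n <- nrow(pr)
  # expected BAF at the region's B count; the mirror removes the allele flip
  state <- probe_tumour_state(profile, flip = FALSE)
  mu_lrr <- expected_lrr(state$copy, contamination, baseline_shift)
  mu_baf <- expected_baf(state$b_tumour, state$copy, state$b_normal,
                         contamination)
  mbaf <- mirror_baf(mu_baf)
  informative <- classify_informative(mbaf, hom_threshold)

  # A zero-cost segmentation must separate differing observed values; imputed
  # (non-informative) entries never enter the segment energies, so an imBAF
  # level change only forces a boundary somewhere between the two observed
  # probes that straddle it. The minimal set: every expected-LRR jump, plus,
  # for each differing pair of consecutive informative probes not already
  # separated by an LRR jump, the leftmost admissible boundary (the DP's
  # tie rule pushes boundaries left).
  tol <- 1e-9
  lrr_cps <- which(abs(diff(mu_lrr)) > tol)  # 0-based boundary index
  obs <- which(informative)                  # 1-based rows
  extra <- integer(0)
  if (length(obs) > 1) {
    vals <- mbaf[obs]
    chg <- which(abs(diff(vals)) > tol)
    for (k in chg) {
      lo <- obs[k]          # leftmost admissible boundary, 0-based
      hi <- obs[k + 1] - 1  # rightmost admissible boundary, 0-based
      if (!any(lrr_cps >= lo & lrr_cps <= hi)) extra <- c(extra, lo)
    }
  }
  sort(unique(c(lrr_cps, extra)))
}

#' True change-points expressed by the noiseless signal
#'
#' Subset of the profile's true change-points that lie within `window` probes
#' of a jump of the expected (noiseless) bivariate series computed by
#' [signal_changepoints()]. Boundaries outside this set cannot be recovered
#' from LRR/imBAF at the given contamination — e.g. copy-neutral germline-LOH
#' borders — and make the honest sensitivity denominator.
#'
#' @inheritParams signal_changepoints
#' @param window Matching half-width in probes. Default 3.
#' @return Integer vector, a subset of `profile$changepoints`.
#' @export
expressed_changepoints <- function(profile, contamination = 0, window = 3,
                                   baseline_shift = NULL,
                                   hom_threshold = 0.95) {
  sig <- signal_changepoints(profile, contamination = contamination,
                             baseline_shift = baseline_shift,
                             hom_threshold = hom_threshold)
  t <- profile$changepoints
  if (!length(sig)) return(integer(0))
  t[vapply(t, function(x) any(abs(sig - x) <= window), TRUE)]
}
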