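---
title: "Bivariate structural-change segmentation of SNP-array tumour profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivariate structural-change segmentation of SNP-array tumour profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivarseg)
```

## The problem

SNP arrays measure two signals at every probe of a tumour sample: the log R
ratio (LRR), the log2 total intensity relative to a diploid reference, and
the B allele frequency (BAF), the fraction of signal attributable to the B
allele. Copy-number alterations shift the LRR; allelic imbalances and loss
of heterozygosity (LOH) shift the BAF. Allele-specific copy-number analysis
starts by cutting the two signals into segments of constant state, and the
quality of everything downstream — purity and ploidy fits, allele-specific
copy calls — hinges on whether those change-points are found.

The difficulty is that the two variables are informative in different
situations: a copy-neutral LOH moves only the BAF, a balanced duplication in
a noisy sample may move only the LRR appreciably, and contamination by
normal cells shrinks both signals towards their diploid values. A univariate
segmentation of either signal misses changes carried by the other; a naive
bivariate one (summing per-variable costs) dilutes changes carried by a
single variable. `bivarseg` implements a bivariate structural change model
that keeps both kinds of change detectable.

## Signal transformation

BAF is symmetric under allele relabelling, so it is first mirrored along the
0.5 axis, `mBAF = |BAF − 0.5| + 0.5` (`mirror_baf()`). Probes in the
homozygous band carry no allelic information inside heterozygous regions and
are removed: a probe is *informative* when its mBAF is observed and below a
homozygosity threshold (`classify_informative()`, default 0.95). The
remainder is the informative mirrored BAF (imBAF). The threshold rule is the
established practice of mBAF pipelines for unpaired samples; a region-aware
classification (keeping homozygous probes inside constitutive LOH stretches)
would need paired normals and is out of scope.

Removing probes would also discard their LRR values, so missing imBAF (and
missing LRR) entries are filled by constant interpolation — each gap takes
the nearest preceding observed value, the head is back-filled
(`impute_constant()`). Constant interpolation keeps imputed values on the
discrete imBAF bands; linear interpolation would insert values between bands
and smear exactly the edges the segmentation is after. The original
observation masks are kept: imputed entries never enter the model's cost.

Chromosomes are processed independently and never concatenated; a
change-point across a chromosome border is meaningless.

## The model and its cost

Within one chromosome the aligned series \((r_k, b_k)\), \(k = 1 \dots n\),
is modelled as piecewise constant in both variables. For a candidate segment
\(s = [t_s, t_{s+1})\), each variable contributes its residual sum of
squares over *observed* entries only,
\[
\mathrm{rss}_{r,s} = \sum_{k \in s,\ \mathrm{obs}} (r_k - \hat\mu_s)^2,
\qquad
\mathrm{rss}_{b,s} = \sum_{k \in s,\ \mathrm{obs}} (b_k - \hat\nu_s)^2 ,
\]
and the segment energy combines them through a weighted Minkowski distance
of order \(p\):
\[
\delta_s = \left(
  \tfrac{l_{r,s}}{l_{r,s}+l_{b,s}}\, \mathrm{rss}_{r,s}^{\,p}
  + \tfrac{l_{b,s}}{l_{r,s}+l_{b,s}}\, \beta\, \mathrm{rss}_{b,s}^{\,p}
\right)^{1/p},
\]
with \(l_{r,s}, l_{b,s}\) the observed counts (`segment_delta()`). The
segmentation cost is \(G(t_1 \dots t_S) = \sum_s \delta_s\)
(`segmentation_cost()`).

The order \(p\) shapes the interaction between the variables. With \(p = 1\)
the cost is a plain (weighted) sum, and a change carried by a single
variable must be large to pay for a boundary. With \(p < 1\) the map
\(x \mapsto x^p\) is steep near zero, so driving *one* variable's RSS close
to zero is strongly rewarded: a strong fit in a single variable beats two
mediocre fits with the same total residual. That is precisely the geometry
needed for copy-neutral LOH (imBAF-only change) and same-allelic-ratio copy
steps (LRR-only change). The defaults are \(p = 1/4\) and \(\beta = 1\).
The weighting by observed counts makes segments dominated by imputed values
cheap in the right way: a variable entirely imputed within a segment gets
weight zero and the energy degenerates cleanly to the other variable.

`beta` rescales the imBAF contribution. The LRR noise level is roughly six
times the imBAF noise level, but their expected mean shifts also differ by
roughly the same order, so the balanced default \(\beta = 1\) works well and
is kept; `beta` is exposed for data that deviate.

## Exact optimisation

For each number of segments \(S = 1 \dots S_{\max}\),
`segment_bivariate()` minimises \(G\) exactly by dynamic programming over
segment end positions, with the recursion
\(C_s(x) = \min_j \{ C_{s-1}(j) + \delta_{(j,x]} \}\). Restricting segments
to at most `max_segment_length` probes bounds the inner minimisation and
brings the complexity from \(O(n^2 S)\) down to
\(O(n \cdot \texttt{max\_segment\_length} \cdot S)\). The inner kernel is
compiled (Rcpp); per-segment energies come from prefix sums, so each lookup
is constant-time. Defaults: `max_segment_length = min(n, 3000)`,
`max_segments = ceiling(n / 10)`.

Numerical choices:

* RSS computed from prefix sums can go slightly negative (or spuriously
  positive) by cancellation; values below `1e-9` of the segment's raw sum of
  squares are clamped to zero, so noiseless piecewise-constant inputs price
  out at exactly zero and `0^p` never produces `NaN`.
* Cost ties in the recursion resolve to the smallest predecessor index,
  giving a deterministic, leftmost change-point vector. On a constant
  stretch whose boundary is only pinned by a later observed imBAF value,
  the boundary therefore lands immediately after the last observed probe of
  the previous level.
* An infeasible configuration
  (`max_segments * max_segment_length < n`) is an error, not a silent
  adjustment.

With every probe observed in both variables the optimal cost is
non-increasing in \(S\) (splitting a segment can only reduce the
superadditive \(p<1\) combination). Under missingness this can fail: the
observed-count weights change when a segment is split, and a split that
isolates a sparsely observed stretch can *raise* the weighted energy. The
package therefore never assumes monotonicity; model selection scores every
\(S\) directly.

## Choosing the number of segments

`select_segments()` maximises a BIC-penalised Gaussian log-likelihood,
\[
\log \tilde L = -\frac{N}{2}\left(1 + \log \frac{2\pi\delta}{N}\right)
 - k\, S \log N ,
\]
where \(\delta\) is the optimal cost for \(S\) segments and \(k\) (default
1) steers sensitivity: smaller \(k\) yields more change-points, and the
selected \(S\) is provably non-increasing in \(k\). Ties resolve towards
fewer segments.

\(N\) is taken as the number of probes of the series. The model treats each
probe as one bivariate observation \(z_k = (r_k, b_k)\), and partial
observation is already folded into \(\delta\) through the observed-count
weights; counting every observed scalar separately would inflate the
likelihood term relative to the penalty and measurably over-segment pure
noise. The pure-noise selection rate the acceptance script reports is
computed under this definition.

A perfect fit (\(\delta = 0\)) is floored at \(N \varepsilon\) before the
logarithm so the criterion stays finite; all zero-cost candidates then tie
in the likelihood term and the penalty picks the smallest \(S\) — which is
how noiseless signals are recovered exactly.

## The synthetic benchmark generator

Real labelled tumour SNP-array data cannot ship with the package, so the
generator provides ground-truthed samples in their place.
`simulate_profile()` lays one alteration per combination of state and
length on a pattern background; `simulate_sample()` realises noisy
observations from the mixture model.

* **Patterns.** `near_diploid` (background 2 copies, heterozygous),
  `near_triploid` / `near_tetraploid` (background 3 / 4 copies),
  `loh_enriched` (diploid with long extra germline-LOH stretches, about a
  quarter of probes), `complex` (all alteration types, including allelic
  imbalance at copies 4–5). Alterations span 10, 20, 40, 80 or 160 probes,
  cover copy numbers 1–5 with and without somatic or germline LOH, and are
  separated by 30 background probes.
* **Signals.** A locus with tumour copy number \(c\) and \(b\) B alleles in
  a sample with normal-cell fraction \(w\) has
  \(\mathrm{LRR} = \log_2\!\big((2w + (1-w)c)/2\big) + \text{shift}\) and
  \(\mathrm{BAF} = (w\,b_N + (1-w)\,b)/(2w + (1-w)c)\), the standard
  two-population mixture; contamination shrinks both towards diploid
  values. The baseline shift recentres the pattern's background at LRR 0,
  as array normalisation does on aneuploid genomes.
* **Noise.** Gaussian, `sd_lrr = 0.30` and `sd_baf = 0.05` by default —
  the LRR noise level is about six times the BAF level, the ratio observed
  on this platform class; absolute levels are configurable. BAF is clamped
  to \([0,1]\) rather than redrawn; the resulting mild heteroscedasticity
  of the homozygous band mimics the real signal and is small enough not to
  affect segmentation. Five percent of probes are non-polymorphic (missing
  BAF); germline genotypes are heterozygous with probability 0.3, forced
  homozygous inside germline-LOH regions.
* **Determinism.** Given a seed, profile and sample are bit-reproducible.

What the generator does **not** emulate: LRR waves and dye bias
(autocorrelated noise), probe-specific variance, subclonal alterations
(an optional cell-fraction multiplier exists for experiments but is off by
default), and platform-specific allele-intensity distortions. Passing
benchmarks here therefore demonstrates correctness of the method under its
own model assumptions, not performance on any particular real cohort.

## Scoring conventions

`score_changepoints()` follows the windowed protocol: a true change-point is
recalled if a prediction lies within 3 probes; a prediction is matched if it
lies within 3 probes of some true change-point, and repeated calls of the
same boundary do not deflate specificity. "Specificity" is thus the
precision-like fraction of matched predictions — the convention that makes
multi-segmentation methods comparable. The trivial boundaries \(t_1 = 0\)
and \(t_{S+1} = n\) are excluded from both sets.

Not every true boundary is visible to LRR/imBAF: a copy-neutral germline-LOH
border moves neither signal (its probes are homozygous, hence
non-informative), and copy-neutral somatic LOH in a *pure* tumour pushes
heterozygous BAF to exactly 0/1, past the homozygosity threshold.
`expressed_changepoints()` computes, from the expected noiseless signal, the
subset of true boundaries a perfect segmenter could recover; benchmark
sensitivities use it as the denominator, while predictions are still matched
against the full truth set so a call at a real-but-invisible border is not
counted as a false positive.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script experiments use: exhaustive-enumeration
cross-checks on 200 random series of up to 24 probes (2–4 segments,
\(p \in \{1, 1/2, 1/4\}\), \(\beta \in \{1/2, 1, 2\}\), up to 30%
missingness per variable); noiseless exact recovery on full-roster samples
of every pattern (3,700–5,100 probes); 50 noisy near-diploid samples at 0%
contamination; a contamination sweep over \{0, 25, 50, 75\}% on 160-probe
alterations with paired seeds (common random numbers across levels); and
200 pure-noise replicates of 150 probes for the model-selection check.
These sizes exercise every code path at full fidelity while keeping a
complete run in minutes on one core.

## Limitations

* The homozygosity threshold is global; constitutive LOH is bridged by
  interpolation rather than modelled, so copy-neutral germline-LOH borders
  are not detectable by design (they need a paired normal or a
  population-frequency model).
* Exactness of the optimisation is per chromosome and per \(S\); the
  selected segmentation is only as good as the BIC trade-off, which `k`
  exposes deliberately.
* Downstream allele-specific copy-number calling (purity/ploidy fitting,
  state assignment) is out of scope: the package ends at change-points and
  per-segment means.

## A minimal session

```{r example, eval = FALSE}
prof <- simulate_profile("near_diploid", seed = 11)
probes <- simulate_sample(prof, contamination = 0.25, seed = 12)
segs <- segment_profile(probes, max_segment_length = 500)
score_changepoints(prof$changepoints, segs$start[segs$start > 0],
                   window = 3,
                   detectable_cps = expressed_changepoints(prof, 0.25))
```
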