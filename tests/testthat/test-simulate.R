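test_that("expected_lrr follows the mixture model", {
  expect_equal(expected_lrr(2), 0)
  expect_equal(expected_lrr(4), 1)
  expect_equal(expected_lrr(1, contamination = 0.5), log2(1.5 / 2))
  expect_equal(expected_lrr(0, contamination = 0), -5)  # floor, not -Inf
  expect_equal(expected_lrr(3, baseline_shift = -0.5), log2(1.5) - 0.5)
  expect_error(expected_lrr(-1), "copy_number")
})

test_that("contamination shrinks LRR towards the diploid 0", {
  for (cn in 0:5) {
    w <- seq(0, 1, by = 0.25)
    vals <- abs(expected_lrr(cn, w))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("expected_baf follows the mixture model and its symmetries", {
  expect_equal(expected_baf(1, 2), 0.5)
  expect_equal(expected_baf(3, 4, n_b_normal = 0, contamination = 1), 0)
  expect_equal(expected_baf(3, 4, n_b_normal = 2, contamination = 1), 1)
  expect_equal(expected_baf(0, 1, n_b_normal = 1, contamination = 0.5), 1 / 3)
  # allele relabelling: b -> c - b, normal 0..2 -> 2 - normal
  for (c in 1:5) for (b in 0:c) for (bn in 0:2) for (w in c(0, 0.3, 0.7)) {
    expect_equal(expected_baf(b, c, bn, w),
                 1 - expected_baf(c - b, c, 2L - bn, w))
  }
  expect_error(expected_baf(0, 0, 1, 0), "undefined")
  expect_error(expected_baf(3, 2), "n_b_tumour")
})

test_that("simulate_profile places alterations and truth change-points", {
  one <- tibble::tibble(copy_number = 3L, n_b_alleles = 1L, loh_type = "none")
  prof <- simulate_profile("near_diploid", lengths = 40, states = one,
                           gap = 480, seed = 1)
  expect_equal(nrow(prof$probes), 1000)
  expect_equal(prof$changepoints, c(480L, 520L))
  expect_equal(sum(prof$probes$copy_number == 3), 40)

  empty <- one[0, ]
  bg <- simulate_profile("near_diploid", states = empty, gap = 200, seed = 1)
  expect_equal(length(bg$changepoints), 0)
  expect_equal(nrow(bg$probes), 200)
})

test_that("true change-points are exactly the state changes", {
  prof <- simulate_profile("complex", seed = 8)
  st <- paste(prof$probes$copy_number, prof$probes$n_b_alleles)
  expect_equal(prof$changepoints, which(st[-1] != st[-length(st)]))
})

test_that("profiles and samples are reproducible given a seed", {
  p1 <- simulate_profile("loh_enriched", seed = 99)
  p2 <- simulate_profile("loh_enriched", seed = 99)
  expect_identical(p1$probes, p2$probes)
  s1 <- simulate_sample(p1, contamination = 0.25, seed = 7)
  s2 <- simulate_sample(p2, contamination = 0.25, seed = 7)
  expect_identical(s1, s2)
})

test_that("germline-LOH regions carry homozygous genotypes", {
  prof <- simulate_profile("loh_enriched", seed = 12)
  g <- prof$probes$genotype[prof$probes$loh_type == "germline"]
  expect_true(length(g) > 0 && all(g %in% c("AA", "BB")))
  bg <- prof$probes$genotype[prof$probes$loh_type == "none"]
  expect_gt(mean(bg == "AB"), 0.2)
  expect_lt(mean(bg == "AB"), 0.4)
})

test_that("noiseless samples hit the expected values exactly", {
  one <- tibble::tibble(copy_number = 2L, n_b_alleles = 1L, loh_type = "none")
  prof <- simulate_profile("near_diploid", lengths = 10, states = one,
                           gap = 45, seed = 3)
  smp <- simulate_sample(prof, sd_lrr = 0, sd_baf = 0, missing_baf_rate = 0,
                         seed = 4)
  expect_true(all(smp$lrr == 0))  # diploid background, shift recentred
  ab <- prof$probes$genotype == "AB"
  expect_true(all(smp$baf[ab] == 0.5))
  bb <- prof$probes$genotype == "BB"
  expect_true(all(smp$baf[bb] == 1.0))
})

test_that("noise, clamping and missingness behave as configured", {
  one <- tibble::tibble(copy_number = 2L, n_b_alleles = 1L,
                        loh_type = "none")[0, ]
  prof <- simulate_profile("near_diploid", states = one, gap = 100000, seed = 5)
  smp <- simulate_sample(prof, sd_lrr = 0.3, sd_baf = 0.05,
                         missing_baf_rate = 0.05, seed = 6)
  expect_equal(sd(smp$lrr), 0.3, tolerance = 0.02)       # Monte-Carlo, n = 1e5
  expect_equal(mean(is.na(smp$baf)), 0.05, tolerance = 0.1)
  expect_true(all(smp$baf >= 0 & smp$baf <= 1, na.rm = TRUE))
})

test_that("subclonal alterations blend with the tumour background state", {
  states <- tibble::tibble(copy_number = 4L, n_b_alleles = 2L,
                           loh_type = "none", cell_fraction = 0.5)
  prof <- simulate_profile("near_diploid", lengths = 40, states = states,
                           gap = 40, seed = 14)
  smp <- simulate_sample(prof, sd_lrr = 0, sd_baf = 0, missing_baf_rate = 0,
                         seed = 15)
  inside <- prof$probes$cell_fraction < 1
  # half the tumour cells at copy 4, half diploid: effective copy 3
  expect_equal(unique(smp$lrr[inside]), log2(3 / 2))
  expect_equal(unique(smp$lrr[!inside]), 0)
  ab <- inside & prof$probes$genotype == "AB"
  expect_equal(unique(smp$baf[ab]), 0.5)  # balanced alteration stays at 0.5
})

test_that("signal_changepoints marks LOH borders invisible to LRR/imBAF", {
  states <- tibble::tibble(
    copy_number = c(3L, 2L), n_b_alleles = c(1L, 0L),
    loh_type = c("none", "germline"))
  prof <- simulate_profile("near_diploid", lengths = 40, states = states,
                           gap = 50, shuffle = FALSE, seed = 10)
  sig <- signal_changepoints(prof)
  det <- expressed_changepoints(prof)
  # copy-3 borders carry an LRR jump; germline-LOH borders carry nothing
  alt <- prof$alterations
  borders <- function(rows) sort(c(rows$start_probe,
                                   rows$start_probe + rows$n_probes))
  cn3 <- borders(alt[alt$loh_type == "none", ])
  loh <- borders(alt[alt$loh_type == "germline", ])
  expect_true(all(cn3 %in% det))
  expect_false(any(loh %in% det))
  expect_true(all(det %in% prof$changepoints))
  expect_true(all(cn3 %in% sig))
})
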