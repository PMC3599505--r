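test_that("segment_stats computes observed-only means and RSS", {
  s <- make_series(c(1, 1, 1, 1), runif(4, 0.5, 1))
  st <- segment_stats(s, 0, 4)
  expect_equal(st$rss_lrr, 0)
  expect_equal(st$mean_lrr, 1)

  s2 <- make_series(c(0, 2), c(0.5, 0.5))
  st2 <- segment_stats(s2, 0, 2)
  expect_equal(st2$mean_lrr, 1)
  expect_equal(st2$rss_lrr, 2)

  s3 <- make_series(c(0, 0, 0), c(0.6, 0.6, 0.8),
                    imbaf_obs = c(TRUE, FALSE, TRUE))
  st3 <- segment_stats(s3, 0, 3)
  expect_equal(st3$n_imbaf, 2L)
  expect_equal(st3$mean_imbaf, 0.7)
  expect_equal(st3$rss_imbaf, 0.02)

  expect_error(segment_stats(s3, 2, 2), "invalid segment")
  expect_error(segment_stats(s3, -1, 2), "invalid segment")
})

test_that("tiling_stats agrees with per-segment segment_stats", {
  withr::with_seed(5, {
    s <- random_series(30)
    t <- c(0, 7, 15, 16, 30)
    whole <- tiling_stats(s, t)
    each <- purrr::map2_dfr(t[-length(t)], t[-1], ~segment_stats(s, .x, .y))
    expect_equal(whole, each, tolerance = 1e-12)
  })
})

test_that("segment_delta evaluates the weighted Minkowski energy", {
  st <- function(rss_r, rss_b, lr, lb)
    tibble::tibble(rss_lrr = rss_r, rss_imbaf = rss_b, n_lrr = lr, n_imbaf = lb)
  for (p in c(1, 0.5, 0.25))
    expect_equal(segment_delta(st(1, 1, 4, 4), p = p), 1)
  expect_equal(segment_delta(st(16, 0, 3, 3), p = 0.5), 4)
  # all imBAF missing in the segment: weights collapse to LRR alone
  expect_equal(segment_delta(st(7.3, 0, 5, 0), p = 0.25), 7.3)
  expect_equal(segment_delta(st(0, 0, 4, 4), p = 0.25), 0)
  expect_error(segment_delta(st(1, 1, 2, 2), p = 0), "positive")
})

test_that("segmentation_cost vanishes exactly where the model fits exactly", {
  s <- make_series(rep(0.3, 8), rep(0.7, 8))
  expect_equal(segmentation_cost(s, c(0, 8)), 0)
  expect_equal(segmentation_cost(s, 0:8), 0)  # single-point segments
  s2 <- make_series(c(0, 0, 2, 2), rep(0.6, 4))
  expect_equal(segmentation_cost(s2, c(0, 2, 4)), 0)
  expect_error(segmentation_cost(s2, c(0, 5, 4)), "changepoints")
  expect_error(segmentation_cost(s2, c(1, 4)), "changepoints")
})

test_that("the DP recovers trivial optima and respects constraints", {
  s <- make_series(rep(1, 12), rep(0.6, 12))
  fit <- segment_bivariate(s, max_segments = 3)
  expect_equal(fit$results[[1]]$total_cost, 0)
  expect_equal(fit$results[[1]]$changepoints, c(0L, 12L))

  step <- make_series(c(rep(0, 20), rep(5, 20)), rep(0.6, 40))
  f2 <- segment_bivariate(step, max_segments = 2)
  expect_equal(f2$results[[2]]$total_cost, 0)
  expect_equal(f2$results[[2]]$changepoints, c(0L, 20L, 40L))

  expect_error(segment_bivariate(s, max_segments = 2, max_segment_length = 5),
               "infeasible")
  withr::with_seed(1, {
    f3 <- segment_bivariate(random_series(12), max_segments = 3,
                            max_segment_length = 5)
    for (r in f3$results)
      expect_true(all(diff(r$changepoints) <= 5))
    expect_equal(vapply(f3$results, `[[`, 1L, "n_segments"), 3L)  # S<3 infeasible
  })
})

test_that("DP cost equals exhaustive enumeration on random series", {
  withr::with_seed(42, {
    for (i in 1:12) {
      n <- sample(8:16, 1)
      S <- sample(2:4, 1)
      p <- sample(c(1, 0.5, 0.25), 1)
      beta <- sample(c(0.5, 1, 2), 1)
      s <- random_series(n)
      fit <- segment_bivariate(s, max_segments = S, max_segment_length = n,
                               p = p, beta = beta)
      dp <- fit$results[[length(fit$results)]]
      expect_equal(dp$total_cost, brute_force_min_cost(s, S, p, beta),
                   tolerance = 1e-9)
      # the reported changepoints price out at the reported cost
      expect_equal(segmentation_cost(s, dp$changepoints, p, beta),
                   dp$total_cost, tolerance = 1e-9)
    }
  })
})

test_that("optimal cost is non-increasing in S on fully observed series", {
  withr::with_seed(9, {
    for (i in 1:5) {
      s <- make_series(rnorm(25), 0.5 + abs(rnorm(25, 0, 0.1)))
      fit <- segment_bivariate(s, max_segments = 6, max_segment_length = 25)
      costs <- vapply(fit$results, `[[`, 0, "total_cost")
      expect_true(all(diff(costs) <= 1e-12))
    }
  })
})

test_that("with beta = 1 the two variables are exchangeable", {
  withr::with_seed(13, {
    x <- rnorm(20); y <- rnorm(20)
    a <- make_series(x, y)
    b <- make_series(y, x)
    fa <- segment_bivariate(a, max_segments = 4, beta = 1)
    fb <- segment_bivariate(b, max_segments = 4, beta = 1)
    expect_equal(vapply(fa$results, `[[`, 0, "total_cost"),
                 vapply(fb$results, `[[`, 0, "total_cost"), tolerance = 1e-12)
  })
})

test_that("all-missing imBAF reduces to univariate segmentation of LRR", {
  withr::with_seed(21, {
    lrr <- rnorm(14)
    s <- make_series(lrr, rep(0.6, 14), imbaf_obs = FALSE)
    fit <- segment_bivariate(s, max_segments = 3, max_segment_length = 14)
    # independent univariate oracle: min over tilings of summed LRR RSS
    rss <- function(x) if (length(x) < 2) 0 else sum((x - mean(x))^2)
    splits <- utils::combn(13, 2)
    uni <- min(apply(splits, 2, function(t)
      rss(lrr[1:t[1]]) + rss(lrr[(t[1] + 1):t[2]]) + rss(lrr[(t[2] + 1):14])))
    expect_equal(fit$results[[3]]$total_cost, uni, tolerance = 1e-9)
  })
})

test_that("rescaling both variables scales every cost by c^2, keeping optima", {
  withr::with_seed(31, {
    s <- random_series(18)
    c0 <- 3.7
    s2 <- s
    s2$lrr <- s$lrr * c0
    s2$imbaf <- s$imbaf * c0
    f1 <- segment_bivariate(s, max_segments = 3, max_segment_length = 18)
    f2 <- segment_bivariate(s2, max_segments = 3, max_segment_length = 18)
    for (k in seq_along(f1$results)) {
      expect_equal(f2$results[[k]]$total_cost, c0^2 * f1$results[[k]]$total_cost,
                   tolerance = 1e-9)
      expect_equal(f2$results[[k]]$changepoints, f1$results[[k]]$changepoints)
    }
  })
})

test_that("cost ties resolve to the leftmost change-points", {
  s <- make_series(rep(0, 10), rep(0.6, 10))
  fit <- segment_bivariate(s, max_segments = 2)
  expect_equal(fit$results[[2]]$changepoints, c(0L, 1L, 10L))
})
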