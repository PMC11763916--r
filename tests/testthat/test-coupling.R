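test_that("ratio binning averages within half-open sub-intervals", {
  s <- tibble::tibble(ratio = c(0.1, 0.1, 0.9), gpp_day = c(2, 4, 10))
  b <- bin_by_ratio(s, "gpp_day", n_bins = 2)
  expect_equal(b$bin_mean, c(3, 10))
  expect_equal(b$bin_count, c(2, 1))
  expect_equal(b$bin_center, c(0.25, 0.75))

  # a value on an interior edge belongs to the right bin
  s_edge <- tibble::tibble(ratio = c(0.5, 0.499999), x = c(1, 2))
  b_edge <- bin_by_ratio(s_edge, "x", n_bins = 2)
  expect_equal(b_edge$bin[b_edge$bin_mean == 1], 2L)
  expect_equal(b_edge$bin[b_edge$bin_mean == 2], 1L)

  # constant variable: every populated bin mean equals the constant
  s_const <- tibble::tibble(ratio = runif(500, 0.01, 0.99), x = 7)
  expect_true(all(bin_by_ratio(s_const, "x", 50)$bin_mean == 7))

  # counts conserve observations
  sim <- tiny_sim(seed = 9)
  kept <- filter_ratio(sim$summaries)$kept
  b_sim <- bin_by_ratio(kept, "le", 200)
  expect_equal(sum(b_sim$bin_count), sum(!is.na(kept$le)))

  expect_error(bin_by_ratio(s, "gpp_day", n_bins = 1), "n_bins")
  expect_error(bin_by_ratio(tibble::tibble(ratio = 1.2, x = 1), "x", 10),
               "outside")
})

test_that("polynomial fit recovers a linear coupling exactly", {
  # ratios placed exactly at bin centers so bin means pair with centers
  centers <- seq(0.01, 0.99, by = 0.02)
  s <- tibble::tibble(ratio = sample(centers, 2000, replace = TRUE))
  s$y <- 2 * s$ratio + 1
  m <- fit_coupling_curve(bin_by_ratio(s, "y", 50), "polynomial", degree = 1)
  co <- tidy(m)
  expect_equal(co$estimate, c(1, 2), tolerance = 1e-8)
  expect_equal(m$goodness, 1, tolerance = 1e-8)
  expect_equal(predict(m, c(0.2, 0.8)), c(1.4, 2.6), tolerance = 1e-8)
})

test_that("random-forest coupling fits are reproducible given the seed", {
  sim <- tiny_sim(seed = 13)
  kept <- filter_ratio(sim$summaries)$kept
  b <- bin_by_ratio(kept, "gpp_day", 100)
  m1 <- fit_coupling_curve(b, "random_forest", num_trees = 100, seed = 42)
  m2 <- fit_coupling_curve(b, "random_forest", num_trees = 100, seed = 42)
  g <- seq(0.2, 0.95, length.out = 50)
  expect_identical(predict(m1, g), predict(m2, g))
  expect_gt(m1$goodness, 0.8)
})

test_that("too few populated bins is a fit error", {
  s <- tibble::tibble(ratio = c(0.1, 0.3, 0.5), y = 1:3)
  expect_error(fit_coupling_curve(bin_by_ratio(s, "y", 10), degree = 6),
               "populated bins")
})

test_that("peak location finds the analytic extremum and flags monotone curves", {
  s <- tibble::tibble(ratio = runif(5000, 0.02, 0.98))
  s$y <- -(s$ratio - 0.94)^2
  m <- fit_coupling_curve(bin_by_ratio(s, "y", 200), degree = 2)
  pk <- peak_location(m)
  expect_equal(pk$ratio, 0.94, tolerance = 2e-3)
  expect_false(pk$boundary)

  s$y2 <- s$ratio  # strictly increasing
  m2 <- fit_coupling_curve(bin_by_ratio(s, "y2", 200), degree = 1)
  expect_warning(pk2 <- peak_location(m2), "boundary")
  expect_true(pk2$boundary)
  expect_equal(pk2$ratio, m2$fit_domain[2])

  # NEE-type trough is found with direction = "min"
  s$y3 <- (s$ratio - 0.94)^2
  m3 <- fit_coupling_curve(bin_by_ratio(s, "y3", 200), degree = 2)
  expect_equal(peak_location(m3, direction = "min")$ratio, 0.94,
               tolerance = 2e-3)

  expect_error(peak_location(m, grid = c(0.001, 0.5)), "domain")
})

test_that("fitted curves recover the generator's prescribed peak and shape", {
  sim <- tiny_sim(seed = 17, n_sites = 8, years = 2000:2005)
  kept <- filter_ratio(sim$summaries)$kept
  b <- bin_by_ratio(kept, "gpp_day", 200)
  m <- fit_coupling_curve(b, "polynomial", degree = 6)
  rep <- truth_report(sim, coupling_models = list(gpp_day = m))
  expect_lt(rep$coupling$rmse_frac, 0.10)
  expect_lt(rep$coupling$peak_abs_err, 0.01)
  expect_gt(m$goodness, 0.95)
})

test_that("between-group discrepancy is zero for identical groups and tracks offsets", {
  set.seed(31)
  base <- tibble::tibble(ratio = runif(4000, 0.05, 0.95))
  base$y <- sin(base$ratio * 3) + rnorm(4000, 0, 0.01)
  two <- dplyr::bind_rows(
    dplyr::mutate(base, g = "a"),
    dplyr::mutate(base, g = "b")
  )
  b <- bin_by_ratio(two, "y", 50, group_by = "g")
  d <- between_group_discrepancy(b, "a", "b")
  expect_true(all(d$profile$diff == 0))
  expect_equal(d$mean_abs_diff_below_0p7, 0)

  # a constant injected offset appears in every bin
  two_off <- dplyr::bind_rows(
    dplyr::mutate(base, g = "a"),
    dplyr::mutate(base, y = y + 0.5, g = "b")
  )
  b_off <- bin_by_ratio(two_off, "y", 50, group_by = "g")
  d_off <- between_group_discrepancy(b_off, "a", "b")
  expect_equal(mean(d_off$profile$diff), 0.5, tolerance = 1e-6)

  # sampling-error scaling: discrepancy shrinks roughly as 1/sqrt(n)
  disc_at_n <- function(n, seed) {
    set.seed(seed)
    df <- dplyr::bind_rows(
      tibble::tibble(ratio = runif(n, 0.05, 0.95), y = rnorm(n), g = "a"),
      tibble::tibble(ratio = runif(n, 0.05, 0.95), y = rnorm(n), g = "b")
    )
    between_group_discrepancy(bin_by_ratio(df, "y", 10, group_by = "g"),
                              "a", "b")$mean_abs_diff_below_0p7
  }
  small <- mean(vapply(1:8, function(s) disc_at_n(400, s), numeric(1)))
  large <- mean(vapply(1:8, function(s) disc_at_n(6400, s), numeric(1)))
  expect_gt(small / large, 2.5)  # theory: 4x
})

test_that("coupling model summaries expose goodness and domain", {
  sim <- tiny_sim(seed = 19)
  kept <- filter_ratio(sim$summaries)$kept
  m <- fit_coupling_curve(bin_by_ratio(kept, "le", 100))
  g <- glance(m)
  expect_equal(g$variable, "le")
  expect_true(g$domain_lo < g$domain_hi)
  expect_s3_class(autoplot(m), "ggplot")
})
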