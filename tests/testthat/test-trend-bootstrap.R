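test_that("critical r matches the t-distribution closed form", {
  # 18 yearly points at alpha 0.05: the 0.47 significance band
  expect_equal(round(critical_r(18, 0.05), 2), 0.47)
  # df = 1: verify against a direct t-quantile computation
  t1 <- qt(0.975, df = 1)
  expect_equal(critical_r(3, 0.05), t1 / sqrt(t1^2 + 1), tolerance = 1e-12)
  expect_equal(critical_r(3, 0.05), 0.997, tolerance = 1e-3)
  # monotone: larger alpha and larger n both lower the threshold
  expect_lt(critical_r(18, 0.10), critical_r(18, 0.05))
  ns <- c(5, 10, 18, 50, 200)
  expect_true(all(diff(critical_r(ns, 0.05)) < 0))
  expect_error(critical_r(2), "n_points")
})

test_that("signed r takes the slope sign on the root of R-squared", {
  expect_equal(signed_r(2, 0.25), 0.5)
  expect_equal(signed_r(-1, 1), -1)
  expect_equal(signed_r(0, 0), 0)
  # odd in the slope sign
  expect_equal(signed_r(-3, 0.49), -signed_r(3, 0.49))
  expect_error(signed_r(1, 1.2), "r_squared")
})

test_that("bootstrap trend curves are deterministic and order-invariant", {
  sim <- tiny_sim(seed = 37, n_sites = 12, years = 2000:2008)
  kept <- filter_ratio(sim$summaries)$kept
  spec <- bootstrap_spec(n_bins = 20, B = 25, sample_size = 400,
                         min_unique_sites = 5, seed = 11)
  t1 <- suppressMessages(bootstrap_trends(kept, "ta_day", spec))
  t2 <- suppressMessages(bootstrap_trends(kept, "ta_day", spec))
  expect_identical(t1$r_samples, t2$r_samples)

  shuffled <- kept[sample(nrow(kept)), ]
  t3 <- suppressMessages(bootstrap_trends(shuffled, "ta_day", spec))
  expect_identical(t1$r_samples, t3$r_samples)

  expect_true(all(abs(t1$r_samples) <= 1, na.rm = TRUE))
  expect_equal(t1$critical_r, critical_r(9, 0.05))
})

test_that("bins violating the unique-site constraint are skipped", {
  sim <- tiny_sim(seed = 41, n_sites = 3, years = 2000:2004)
  kept <- filter_ratio(sim$summaries)$kept
  spec <- bootstrap_spec(n_bins = 10, B = 10, sample_size = 100,
                         min_unique_sites = 2, seed = 1)
  tc <- suppressMessages(bootstrap_trends(kept, "le", spec))
  # sparse extreme bins hold fewer than 2 of the 3 sites and must be absent
  per_bin_sites <- kept |>
    dplyr::mutate(bin = pmin(findInterval(ratio, seq(0, 1, 0.1),
                                          rightmost.closed = TRUE), 10)) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(ns = dplyr::n_distinct(site_id))
  eligible <- per_bin_sites$bin[per_bin_sites$ns >= 2]
  expect_setequal(tc$summary$bin, eligible)

  spec_all <- bootstrap_spec(n_bins = 10, B = 5, sample_size = 50,
                             min_unique_sites = 4, seed = 1)
  expect_error(suppressMessages(bootstrap_trends(kept, "le", spec_all)),
               "No bin")
})

test_that("an injected trend is detected only where it was injected", {
  # trend confined to one RATIO band; elsewhere flat
  trends <- default_trends()
  trends$le <- function(x) ifelse(x >= 0.75 & x < 0.90, 40, 0)
  cfg <- synth_config(n_sites = 15, latitudes = seq(-50, 60, length.out = 15),
                      years = 1997:2014, trends = trends, seed = 43)
  sim <- simulate_daily_summaries(cfg)
  kept <- filter_ratio(sim$summaries)$kept
  tc <- suppressMessages(bootstrap_trends(
    kept, "le",
    bootstrap_spec(n_bins = 20, B = 60, sample_size = 2000,
                   min_unique_sites = 8, seed = 43)))
  s <- tc$summary
  inside <- s$bin_center > 0.75 & s$bin_center < 0.90
  outside <- s$bin_center < 0.70 | s$bin_center > 0.95
  expect_true(all(s$r_median[inside] > tc$critical_r))
  expect_true(all(abs(s$r_median[outside & s$n_records > 500]) <
                    tc$critical_r))
})

test_that("curve features read off constructed crossings and vertices", {
  centers <- seq(0.31, 0.99, by = 0.02)
  lin <- tibble::tibble(bin_center = centers, r_median = centers - 0.55)
  f_lin <- curve_features(lin)
  expect_equal(f_lin$zero_crossing, 0.55, tolerance = 1e-6)

  quad <- tibble::tibble(bin_center = centers,
                         r_median = -(centers - 0.90)^2 + 0.6)
  f_quad <- curve_features(quad)
  expect_equal(f_quad$vertex, 0.90, tolerance = 1e-3)

  # all-positive curve: no crossing reported
  pos <- tibble::tibble(bin_center = centers, r_median = 0.5 + centers / 10)
  expect_null(curve_features(pos)$zero_crossing)

  expect_error(curve_features(lin[1:3, ]), "at least 5")
})

test_that("trend summaries expose quantiles and tidy/glance methods", {
  sim <- tiny_sim(seed = 47, n_sites = 12, years = 2000:2008)
  kept <- filter_ratio(sim$summaries)$kept
  tc <- suppressMessages(bootstrap_trends(
    kept, "co2", bootstrap_spec(n_bins = 20, B = 30, sample_size = 500,
                                min_unique_sites = 5, seed = 3)))
  td <- tidy(tc)
  expect_true(all(c("bin_center", "r_median", "r_q05", "r_q95",
                    "frac_sig_pos") %in% names(td)))
  expect_true(all(td$r_q05 <= td$r_median & td$r_median <= td$r_q95))
  # CO2 rises everywhere in the generator: strongly positive r throughout
  expect_true(all(td$r_median[td$n_records > 500] > 0.5))
  g <- glance(tc)
  expect_equal(g$variable, "co2")
  expect_s3_class(autoplot(tc), "ggplot")
})
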