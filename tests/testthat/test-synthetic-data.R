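test_that("identical seeds give identical networks, different seeds differ", {
  s1 <- tiny_sim(seed = 71)
  s2 <- tiny_sim(seed = 71)
  expect_identical(s1$summaries, s2$summaries)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- tiny_sim(seed = 72)
  expect_false(identical(s1$summaries$ratio, s3$summaries$ratio))
})

test_that("written network files are byte-identical across same-seed runs", {
  cfg <- synth_config(n_sites = 2, latitudes = c(10, 50), years = 2005L,
                      seed = 73)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_sim_network(simulate_half_hourly(cfg), d1)
  write_sim_network(simulate_half_hourly(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_true(file.exists(file.path(d1, "truth.json")))
})

test_that("engineered out-of-range share matches the filter's operating point", {
  sim <- tiny_sim(seed = 79, n_sites = 10, years = 2000:2003)
  flt <- filter_ratio(sim$summaries)
  n <- nrow(sim$summaries)
  tol <- 3 * sqrt(0.234 * 0.766 / n)
  expect_lt(abs(flt$discarded_fraction - 0.234), tol)
  # kept ratios strictly inside the unit interval
  expect_true(all(flt$kept$ratio > 0 & flt$kept$ratio < 1))
  # a zero setting produces no out-of-range days at all
  clean <- simulate_daily_summaries(
    tiny_config(seed = 80, target_out_of_range_fraction = 0))
  expect_equal(filter_ratio(clean$summaries)$discarded_fraction, 0)
})

test_that("noiseless couplings are recovered exactly from bin means", {
  couplings <- default_couplings()
  cfg <- synth_config(n_sites = 6, latitudes = seq(-30, 50, length.out = 6),
                      years = 2004:2005, noise_frac = 1e-12,
                      site_effect_frac = 1e-12,
                      target_out_of_range_fraction = 0, seed = 83)
  sim <- simulate_daily_summaries(cfg)
  kept <- filter_ratio(sim$summaries)$kept
  b <- bin_by_ratio(kept, "le", 100)
  # per-bin means must sit on the prescribed curve (evaluated per record)
  truth_fn <- couplings$le
  per_bin_truth <- kept |>
    dplyr::mutate(bin = pmin(findInterval(ratio, seq(0, 1, 0.01),
                                          rightmost.closed = TRUE), 100)) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(m = mean(truth_fn(ratio)))
  j <- dplyr::inner_join(tibble::as_tibble(b), per_bin_truth, by = "bin")
  expect_equal(j$bin_mean, j$m, tolerance = 1e-6)
})

test_that("generated day lengths follow solar geometry", {
  cfg <- synth_config(n_sites = 2, latitudes = c(0, 68), years = 2005L,
                      seed = 89)
  sim <- simulate_daily_summaries(cfg)
  eq <- dplyr::filter(sim$summaries, site_id == "SY-001")
  # equator: day length pinned near 12 h all year
  expect_true(all(abs(eq$day_length - 12) < 0.5))
  # high latitude: strong seasonal cycle
  hi <- dplyr::filter(sim$summaries, site_id == "SY-002")
  expect_gt(max(hi$day_length), 20)
  expect_lt(min(hi$day_length), 5)
})

test_that("half-hourly realization reproduces the daily aggregates", {
  sim <- tiny_hh(seed = 97, latitudes = c(-35, 20), years = 2005L, n_sites = 2)
  lab <- partition_day_night(sim$records)
  # drop the summarizer's own per-period le column so the suffixes below
  # unambiguously tag the two pipelines
  ds <- dplyr::select(summarize_daily(lab), -le_day)
  m <- dplyr::inner_join(ds, sim$summaries, by = c("site_id", "date"),
                         suffix = c("_hh", "_day"))
  expect_equal(m$ratio_hh, m$ratio_day, tolerance = 1e-9)
  expect_equal(m$ta_day_hh, m$ta_day_day, tolerance = 1e-9)
  expect_equal(m$gpp_day_hh, m$gpp_day_day, tolerance = 1e-6)
  expect_equal(m$precip_hh, m$precip_day, tolerance = 1e-9)
  # the daily LE total is preserved except on engineered negative-ratio days,
  # where the nocturnal flux is deliberately distorted to break the interval
  ok <- m$ratio_day > 0
  expect_equal(m$le_hh[ok], m$le_day[ok], tolerance = 1e-6)
  # slot-count day length within one slot of the astronomical value
  expect_lt(max(abs(m$day_length_hh - m$day_length_day)), 1.01)
})

test_that("daily water balance closes for every site-day", {
  sim <- tiny_sim(seed = 101)
  s <- sim$summaries
  le_mm <- s$le * sim$truth$latent_heat_mm_per_unit
  residual <- s$precip - s$runoff_mm - s$delta_swc_mm - le_mm
  expect_lt(max(abs(residual)), 1e-9)
  expect_true(all(s$runoff_mm >= 0))
})

test_that("truth report flags artifacts from a different run", {
  sim <- tiny_sim(seed = 103)
  kept <- filter_ratio(sim$summaries)$kept
  m <- fit_coupling_curve(bin_by_ratio(kept, "le", 100), degree = 6)
  attr(m, "run_id") <- "sim-other"
  expect_error(truth_report(sim, coupling_models = list(le = m)), "run_id")
})

test_that("config validation rejects impossible settings", {
  expect_error(synth_config(n_sites = 2, latitudes = 0), "length")
  expect_error(synth_config(target_out_of_range_fraction = 1.2))
  expect_error(synth_config(ratio_sd = 0))
  expect_error(default_trends(crossing = 0.9, vertex = 0.8))
})
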