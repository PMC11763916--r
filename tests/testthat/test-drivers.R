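make_driver_table <- function(n, target_fun, seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(
    site_id = sample(sprintf("S%02d", 1:10), n, replace = TRUE),
    date = as.Date("2005-01-01") + sample(0:364, n, replace = TRUE),
    day_length = runif(n, 8, 16),
    lai = runif(n, 0.2, 6),
    delta_t = runif(n, 2, 10),
    precip = rexp(n, 0.5),
    swc = runif(n, 5, 40),
    co2 = runif(n, 380, 420),
    wetness_index = runif(n, 0.2, 2),
    vpd = runif(n, 1, 12),
    ws = runif(n, 0.5, 8)
  )
  d$ratio <- target_fun(d)
  d
}

test_that("a prescribed dominant driver is ranked first", {
  d <- make_driver_table(2000, function(d)
    plogis(1.5 * (d$lai - 3)) * 0.6 + 0.2 + rnorm(nrow(d), 0, 0.01))
  imp <- screen_contributors(d, seed = 5, num_trees = 150)
  expect_equal(imp$factor[1], "lai")
  expect_gt(imp$importance[1], 0.5)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
})

test_that("no factor explains a target independent of all of them", {
  d <- make_driver_table(1500, function(d) runif(nrow(d), 0.2, 0.9))
  imp <- screen_contributors(d, seed = 7, num_trees = 150)
  # the forest finds nothing to explain: out-of-bag R2 stays at noise level
  expect_lt(attr(imp, "oob_r_squared"), 0.05)
  # contrast: a driven target is well explained
  d2 <- make_driver_table(1500, function(d)
    plogis(d$lai - 3) * 0.6 + 0.2 + rnorm(nrow(d), 0, 0.02))
  imp2 <- screen_contributors(d2, seed = 7, num_trees = 150)
  expect_gt(attr(imp2, "oob_r_squared"), 0.8)
})

test_that("constant predictors get zero importance with a warning", {
  d <- make_driver_table(600, function(d) d$vpd / 12 + rnorm(nrow(d), 0, 0.02))
  d$co2 <- 400
  expect_warning(imp <- screen_contributors(d, seed = 3, num_trees = 100),
                 "co2")
  expect_equal(imp$importance[imp$factor == "co2"], 0)
  expect_equal(imp$factor[1], "vpd")
})

test_that("screening is deterministic given the seed and needs enough rows", {
  d <- make_driver_table(500, function(d) d$lai / 6 + rnorm(nrow(d), 0, 0.05))
  i1 <- screen_contributors(d, seed = 11, num_trees = 100)
  i2 <- screen_contributors(d, seed = 11, num_trees = 100)
  expect_identical(i1, i2)
  expect_error(screen_contributors(d[1:50, ], seed = 1), "100")
})

test_that("the LAI-RATIO curve tracks a deterministic relation exactly", {
  lai <- seq(0, 2, length.out = 400)
  ratio <- 0.5 + 0.1 * lai
  cur <- lai_ratio_curve(lai, ratio, n_bins = 10)
  expect_equal(cur$mean_ratio, 0.5 + 0.1 * cur$lai_bin_center,
               tolerance = 0.011)  # bin means sit on the line at bin centers
  expect_true(all(cur$sd_ratio < 0.006, na.rm = TRUE))
  expect_equal(attr(cur, "monotone_trend"), 1)

  # constant LAI collapses to a single populated bin
  cc <- lai_ratio_curve(rep(1.5, 50), runif(50, 0.4, 0.6))
  expect_equal(nrow(cc), 1)

  expect_error(lai_ratio_curve(numeric(0), numeric(0)), "No complete")
  expect_error(lai_ratio_curve(1:3, 1:2), "equal length")
})

test_that("the generator's LAI link shows up as a rising LAI-RATIO curve", {
  sim <- tiny_sim(seed = 53, n_sites = 12, years = 2004:2006)
  kept <- filter_ratio(sim$summaries)$kept
  kept <- dplyr::left_join(kept,
                           dplyr::select(sim$metadata, site_id, lai),
                           by = "site_id")
  cur <- lai_ratio_curve(kept$lai, kept$ratio, n_bins = 8)
  expect_gt(attr(cur, "monotone_trend"), 0.8)
  expect_true(all(cur$mean_ratio > 0 & cur$mean_ratio < 1))
  expect_s3_class(autoplot(cur), "ggplot")
})

test_that("wetness index is P over PET with the arid boundary excluded", {
  expect_equal(wetness_index(400, 800), 0.5)
  expect_equal(wetness_index(750, 750), 1)
  expect_equal(wetness_index(0, 500), 0)
  expect_error(wetness_index(100, 0), "positive")
  # 0.5 is the boundary: arid means strictly below
  expect_false(wetness_index(400, 800) < 0.50)
})

test_that("Hargreaves PET is physically sensible", {
  doy <- 172  # near northern solstice
  pet_trop <- pet_hargreaves(10, doy, tmean = 26, trange = 9)
  pet_cold <- pet_hargreaves(60, 15, tmean = -5, trange = 4)
  expect_gt(pet_trop, 2)   # humid tropics: a few mm per day
  expect_lt(pet_trop, 10)
  expect_lt(pet_cold, pet_trop)
  expect_gte(pet_cold, 0)
  # extraterrestrial radiation: zero in polar night, large at the summer pole
  expect_equal(extraterrestrial_radiation(80, 355), 0, tolerance = 1e-6)
  expect_gt(extraterrestrial_radiation(80, 172), 30)
})

test_that("driver_table assembles exactly the nine factors plus target", {
  sim <- tiny_sim(seed = 59)
  kept <- filter_ratio(sim$summaries)$kept
  d <- driver_table(kept, sim$metadata,
                    lai = dplyr::select(sim$metadata, site_id, lai))
  expect_setequal(setdiff(names(d), c("site_id", "date")),
                  c("day_length", "lai", "delta_t", "precip", "swc", "co2",
                    "wetness_index", "vpd", "ws", "ratio"))
  expect_false(anyNA(d$ratio))
  expect_true(all(d$wetness_index > 0))
  # annual LAI joined to every site-day of the site
  by_site <- d |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(n_lai = dplyr::n_distinct(lai))
  expect_true(all(by_site$n_lai == 1))
})
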