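#' Run the full daily-RATIO analysis pipeline
#'
#' Wires the stages end to end on a simulated network (or user-supplied
#' summaries + metadata): open-interval RATIO filtering, coupling-curve fits
#' per EC variable, cross-hemisphere mapping with evaluation, the bootstrap
#' Ta-day trend curve with its features, driver screening, the LAI-RATIO
#' curve, and effect classification at the zonal mean RATIOs. Every stage
#' output is a plain tibble (or list thereof) so each stage is independently
#' re-runnable; the configuration used is echoed into the result. The run is
#' idempotent given fixed seeds.
#'
#' @param sim A `ratioflux_sim` (from [simulate_daily_summaries()]); or `NULL`
#'   to simulate one from `config`.
#' @param config A [synth_config()] used when `sim` is `NULL`.
#' @param coupling_bins Sub-intervals for coupling curves (default 200).
#' @param coupling_family `"polynomial"` or `"random_forest"`.
#' @param degree Polynomial degree (default 6).
#' @param trend_spec A [bootstrap_spec()] for the trend stage.
#' @param map_variables Variables to map across hemispheres (default: all 15).
#' @param driver_max_rows,driver_trees Passed to [screen_contributors()].
#' @param seed Seed for the stages' stochastic components.
#' @return A `ratioflux_report` list: `filter`, `models`, `coupling_glance`,
#'   `mapping`, `trend_curve`, `trend_features`, `importances`, `lai_curve`,
#'   `zones`, `effects`, `truth_recovery`, `params`.
#' @export
run_ratio_pipeline <- function(sim = NULL, config = synth_config(),
                               coupling_bins = 200,
                               coupling_family = "polynomial",
                               degree = 6,
                               trend_spec = bootstrap_spec(B = 200, seed = seed),
                               map_variables = ec_variables(),
                               driver_max_rows = 20000L, driver_trees = 500,
                               seed = 1L) {
  if (coupling_bins < 2) abort("coupling_bins must be at least 2.")
  if (is.null(sim)) sim <- simulate_daily_summaries(config)
  summaries <- sim$summaries
  meta <- sim$metadata

  flt <- filter_ratio(summaries)
  kept <- flt$kept
  kept_meta <- left_join(kept,
                         select(meta, "site_id", "group", "hemisphere",
                                "climate_zone"),
                         by = "site_id")

  # coupling curves (pooled across sites)
  models <- purrr::map(setNames(ec_variables(), ec_variables()), function(v) {
    m <- fit_coupling_curve(bin_by_ratio(kept, v, n_bins = coupling_bins),
                            family = coupling_family, degree = degree,
                            seed = seed)
    attr(m, "run_id") <- sim$truth$run_id
    m
  })
  coupling_glance <- purrr::map_dfr(models, glance)

  # western-hemisphere couplings predict eastern-hemisphere observations
  west <- filter(kept_meta, .data$hemisphere == "western")
  east <- filter(kept_meta, .data$hemisphere == "eastern")
  west_models <- purrr::map(setNames(map_variables, map_variables), function(v) {
    fit_coupling_curve(bin_by_ratio(west, v, n_bins = coupling_bins),
                       family = coupling_family, degree = degree, seed = seed)
  })
  mapped <- map_observations(west_models, east)
  mapping <- evaluate_mapping(mapped, metadata = meta, group_by = "group")

  # bootstrap Ta-day trend curve and its features
  trend <- bootstrap_trends(kept, "ta_day", trend_spec)
  feats <- curve_features(trend)
  attr(feats, "run_id") <- sim$truth$run_id

  # drivers
  drv <- driver_table(kept_meta, meta,
                      lai = select(meta, "site_id", "lai"))
  importances <- screen_contributors(drv, seed = seed,
                                     max_rows = driver_max_rows,
                                     num_trees = driver_trees)
  attr(importances, "run_id") <- sim$truth$run_id
  lai_curve <- lai_ratio_curve(drv$lai, drv$ratio)

  # zonal means and effect labels
  zones <- zone_ratio_summary(kept, meta)
  effects <- classify_effect(zones$mean_ratio, "greening")
  effects$climate_zone <- zones$climate_zone

  recovery <- truth_report(sim, coupling_models = models,
                           trend_features = feats, importances = importances)

  structure(list(
    filter = flt[c("discarded_fraction", "n_discarded")],
    models = models, coupling_glance = coupling_glance,
    mapping = mapping, trend_curve = trend, trend_features = feats,
    importances = importances, lai_curve = lai_curve,
    zones = zones, effects = effects, truth_recovery = recovery,
    params = list(coupling_bins = coupling_bins, family = coupling_family,
                  degree = degree, trend_spec = trend_spec, seed = seed,
                  run_id = sim$truth$run_id)
  ), class = "ratioflux_report")
}

#' @export
print.ratioflux_report <- function(x, ...) {
  cat("<ratioflux_report>", x$params$run_id, "\n")
  cat("  discarded ratio fraction:", round(x$filter$discarded_fraction, 4), "\n")
  cat("  coupling R2 (median):",
      round(median(x$coupling_glance$r.squared), 3), "\n")
  cat("  Ta-day trend: crossing",
      round(x$trend_features$zero_crossing %||% NA_real_, 3),
      " vertex", round(x$trend_features$vertex, 3), "\n")
  cat("  top driver:", x$importances$factor[1], "\n")
  invisible(x)
}

#' Zonal mean daily RATIOs from a FLUXNET2015 archive directory
#'
#' Convenience wrapper for running the daily-RATIO computation on a local
#' FLUXNET2015 download: reads every half-hourly site CSV in `dir` (file names
#' must start with the site id, e.g. `CN-Dan_HH.csv` or the FLX_* convention),
#' labels day/night, summarizes site-days, applies the open-interval filter
#' and reports per-climate-zone mean RATIOs plus the discarded fraction.
#'
#' @param dir Directory with half-hourly CSVs and a `site_metadata.csv`.
#' @param daytime_rule Passed to [partition_day_night()].
#' @param min_coverage Passed to [summarize_daily()].
#' @return A list with `zones` (tibble) and `discarded_fraction`.
#' @export
fluxnet_zone_summary <- function(dir, daytime_rule = "swinpot",
                                 min_coverage = 0.9) {
  meta <- read_site_metadata(file.path(dir, "site_metadata.csv"))
  files <- list.files(dir, pattern = "(_HH|_FULLSET_HH).*\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) abort("No half-hourly CSV files found.")
  summaries <- purrr::map_dfr(files, function(f) {
    sid <- sub("([A-Za-z]{2}-[A-Za-z0-9]{3}).*", "\\1",
               sub("^FLX_", "", basename(f)))
    read_fluxnet_hh(f, site_id = sid) |>
      partition_day_night(method = daytime_rule) |>
      summarize_daily(min_coverage = min_coverage)
  })
  check_site_coverage(summaries, meta)
  flt <- filter_ratio(summaries)
  list(zones = zone_ratio_summary(flt$kept, meta),
       discarded_fraction = flt$discarded_fraction)
}
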