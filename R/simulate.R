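#' Simulate a flux network at site-day resolution
#'
#' The daily-scale workhorse of the generator. For every site-day it draws a
#' latent daily RATIO from the site's LAI-linked Beta distribution, evaluates
#' every prescribed coupling function at that latent RATIO, adds the
#' prescribed temporal trend (slope times centered year), the site offset and
#' observation noise, and computes the day length from solar geometry at the
#' site latitude. A configured share of days is perturbed to a raw ratio
#' outside (0, 1) (negative nocturnal LE); the coupled variables of such days
#' still follow the latent in-range RATIO, so filtering them reproduces the
#' open-interval screen's operating point. Daily water balance
#' `P = dSWC + LE_water + R` is closed by construction: runoff is a fixed
#' fraction of precipitation and the soil-water increment takes up the
#' residual.
#'
#' @param config A [synth_config()].
#' @return A `ratioflux_sim` list with `summaries` (site-day tibble in the
#'   shape produced by [summarize_daily()]), `metadata` (site table) and
#'   `truth` (prescribed curves, trends, LAI link, and `run_id`).
#' @export
simulate_daily_summaries <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  layout <- synth_sites(config)
  meta <- layout$metadata
  years <- config$years
  year_mid <- mean(years)
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  n_days <- length(dates)

  per_site <- vector("list", config$n_sites)
  for (i in seq_len(config$n_sites)) {
    set.seed(child_seed(config$seed, i))
    mu <- meta$mean_ratio[i]
    v <- config$ratio_sd^2
    k <- max(mu * (1 - mu) / v - 1, 0.5)
    latent <- rbeta(n_days, mu * k, (1 - mu) * k)
    # keep strictly inside (0, 1): a latent ratio of exactly 0/1 is unphysical
    latent <- pmin(pmax(latent, 1e-4), 1 - 1e-4)

    oor <- runif(n_days) < config$target_out_of_range_fraction
    high <- runif(n_days) < 0.7   # OOR days: mostly ratio > 1, some < 0
    ratio_raw <- latent
    ratio_raw[oor & high] <- 1 + rexp(sum(oor & high), rate = 1 / 0.15)
    ratio_raw[oor & !high] <- -rexp(sum(oor & !high), rate = 1 / 0.08)

    yr <- as.integer(format(dates, "%Y"))
    yr_c <- yr - year_mid
    df <- tibble(
      site_id = meta$site_id[i], date = dates, year = yr,
      ratio = ratio_raw,
      day_length = geosphere::daylength(meta$latitude[i], doy),
      coverage_fraction = 1, valid = TRUE
    )
    for (v_name in EC_VARS) {
      f <- config$couplings[[v_name]]
      b <- config$trends[[v_name]]
      df[[v_name]] <- f(latent) + b(latent) * yr_c +
        layout$offsets[i, v_name] +
        rnorm(n_days, 0, config$noise_sd[[v_name]])
    }
    df$precip <- pmax(df$precip, 0)
    df$ws <- pmax(0.2, layout$ws_base[i] + rnorm(n_days, 0, 0.8))
    df$delta_t <- df$ta_day - df$ta_night
    # water-balance closure, in mm per day
    le_mm <- df$le * config$latent_heat_mm_per_unit
    df$runoff_mm <- config$runoff_fraction * df$precip
    df$delta_swc_mm <- df$precip - df$runoff_mm - le_mm
    per_site[[i]] <- df
  }

  summaries <- bind_rows(per_site)
  grid <- seq(0.0025, 0.9975, by = 0.005)
  truth <- list(
    run_id = paste0("sim-", config$seed, "-", config$n_sites, "-",
                    min(years), "-", max(years)),
    seed = config$seed,
    coupling_grid = grid,
    coupling_true = lapply(config$couplings[EC_VARS], function(f) f(grid)),
    coupling_peak = attr(config$couplings, "peak") %||% NA_real_,
    trend_true = lapply(config$trends[EC_VARS], function(b) b(grid)),
    trend_features = attr(config$trends, "features"),
    lai_link = tibble(lai = meta$lai, mean_ratio = meta$mean_ratio,
                      site_id = meta$site_id),
    target_out_of_range_fraction = config$target_out_of_range_fraction,
    latent_heat_mm_per_unit = config$latent_heat_mm_per_unit
  )
  structure(list(summaries = summaries, metadata = meta, truth = truth,
                 config = config),
            class = "ratioflux_sim")
}

#' @export
print.ratioflux_sim <- function(x, ...) {
  cat("<ratioflux_sim>", x$truth$run_id, "\n")
  cat("  ", nrow(x$summaries), "site-days across", nrow(x$metadata), "sites\n")
  invisible(x)
}

#' Simulate half-hourly flux-network records
#'
#' Expands the daily generator to 30-min resolution: each site-day's latent
#' RATIO is realized by a diurnal latent-heat profile whose daytime share
#' equals the raw ratio — daytime LE follows the potential-radiation shape,
#' nocturnal LE is uniform (negative on engineered out-of-range days). Air
#' temperature takes its per-period value, carbon fluxes are distributed
#' across their period, and VPD, Rn, CO2 and SWC are held at the daily value,
#' so that [summarize_daily()] recovers the daily generator's aggregates.
#'
#' Intended for small configurations (a few sites, weeks to months); use
#' [simulate_daily_summaries()] for network-scale experiments.
#'
#' @param config A [synth_config()].
#' @return A `ratioflux_sim` list with `records` (half-hourly tibble),
#'   `summaries`, `metadata` and `truth`.
#' @export
simulate_half_hourly <- function(config) {
  sim <- simulate_daily_summaries(config)
  daily <- sim$summaries
  meta <- sim$metadata
  lat <- setNames(meta$latitude, meta$site_id)

  hours <- (0:47) / 2 + 0.25   # slot midpoints
  out <- vector("list", nrow(daily))
  for (j in seq_len(nrow(daily))) {
    d <- daily[j, ]
    doy <- as.integer(format(d$date, "%j"))
    swp <- sw_in_potential(lat[[d$site_id]], doy, hours)
    is_day <- swp > 0
    n_day <- sum(is_day); n_night <- 48L - n_day

    le <- numeric(48)
    r <- d$ratio
    if (n_day == 0L || n_night == 0L) {
      le[] <- d$le / 48           # polar day/night: no partition possible
    } else {
      day_total <- if (r > 0 && r < 1) d$le * r else abs(d$le) * max(abs(r), 0.2)
      night_total <- day_total * (1 - r) / r
      le[is_day] <- day_total * swp[is_day] / sum(swp[is_day])
      le[!is_day] <- night_total / n_night
    }

    nee <- numeric(48); reco <- numeric(48); gpp <- numeric(48)
    if (n_day > 0) {
      w <- swp[is_day] / sum(swp[is_day])
      nee[is_day] <- d$nee_day * w
      reco[is_day] <- d$reco_day / n_day
      gpp[is_day] <- d$gpp_day * w
    }
    if (n_night > 0) {
      nee[!is_day] <- d$nee_night / n_night
      reco[!is_day] <- d$reco_night / n_night
    }
    ta <- ifelse(is_day, d$ta_day, d$ta_night)
    precip <- numeric(48)
    slot <- (j * 13L) %% 48L + 1L     # deterministic rain slot
    precip[slot] <- d$precip

    out[[j]] <- tibble(
      site_id = d$site_id,
      timestamp = as.POSIXct(d$date, tz = "UTC") + (0:47) * 1800,
      date = d$date,
      le = le, nee = nee, reco = reco, gpp = gpp, ta = ta,
      vpd = d$vpd, netrad = d$rn, precip = precip, co2 = d$co2,
      swc = d$swc, sw_in_pot = swp
    )
  }
  sim$records <- bind_rows(out)
  sim
}

#' Write a simulated network to disk in the FLUXNET2015 dialect
#'
#' Emits one half-hourly CSV per site, a site-metadata CSV, and a
#' machine-readable `truth.json` describing the prescribed couplings, trends
#' and LAI link of the run. Output is byte-identical for identical seeds.
#'
#' @param sim A `ratioflux_sim` from [simulate_half_hourly()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_network <- function(sim, dir) {
  if (is.null(sim$records)) {
    abort("write_sim_network() needs a half-hourly simulation; run simulate_half_hourly().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in unique(sim$records$site_id)) {
    write_fluxnet_hh(filter(sim$records, .data$site_id == sid),
                     file.path(dir, paste0(sid, "_HH.csv")))
  }
  readr::write_csv(select(sim$metadata, "site_id", "latitude", "longitude",
                          "igbp_class", "lai"),
                   file.path(dir, "site_metadata.csv"), progress = FALSE)
  truth <- sim$truth
  truth$lai_link <- as.list(truth$lai_link)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Compare fitted artifacts against a simulation's ground truth
#'
#' Computes recovery metrics for whatever fitted artifacts are supplied:
#' RMSE between each fitted coupling curve and the prescribed curve (as a
#' fraction of the curve's range) plus the peak-location error; the errors of
#' recovered trend zero-crossing and vertex; and the Spearman rank agreement
#' between estimated driver importances and the generator's dominant-driver
#' ordering. Artifacts carrying a `run_id` attribute must match the
#' simulation's run id.
#'
#' @param sim A `ratioflux_sim`.
#' @param coupling_models Named list of [fit_coupling_curve()] models.
#' @param trend_features Output of [curve_features()] for Ta-day.
#' @param importances Output of [screen_contributors()].
#' @return A list of tibbles/values of recovery metrics.
#' @export
truth_report <- function(sim, coupling_models = NULL, trend_features = NULL,
                         importances = NULL) {
  check_run <- function(obj) {
    rid <- attr(obj, "run_id")
    if (!is.null(rid) && !identical(rid, sim$truth$run_id)) {
      abort("Fitted artifact does not reference this simulation run (run_id mismatch).")
    }
  }
  out <- list(run_id = sim$truth$run_id)
  if (!is.null(coupling_models)) {
    grid <- sim$truth$coupling_grid
    out$coupling <- purrr::map_dfr(names(coupling_models), function(v) {
      m <- coupling_models[[v]]; check_run(m)
      truth_y <- sim$truth$coupling_true[[v]]
      dom <- m$fit_domain
      in_dom <- grid >= dom[1] & grid <= dom[2]
      pred <- predict(m, grid[in_dom])
      rng <- diff(range(truth_y))
      # the prescribed peak only exists for the unimodal flux/energy curves;
      # matter curves are linear and carry no turning point
      unimodal <- !v %in% EC_MATTER_VARS
      p_true <- if (unimodal) sim$truth$coupling_peak else NA_real_
      p_est <- NA_real_
      if (unimodal) {
        direction <- if (v %in% c("nee", "nee_day")) "min" else "max"
        pk <- suppressWarnings(
          peak_location(m, grid = seq(dom[1], dom[2], by = 5e-4),
                        direction = direction))
        p_est <- pk$ratio
      }
      tibble(variable = v,
             rmse_frac = sqrt(mean((pred - truth_y[in_dom])^2)) / rng,
             peak_true = p_true, peak_est = p_est,
             peak_abs_err = abs(p_est - p_true))
    })
  }
  if (!is.null(trend_features)) {
    check_run(trend_features)
    tf <- sim$truth$trend_features
    out$trend <- tibble(
      crossing_true = tf[["crossing"]], crossing_est = trend_features$zero_crossing,
      crossing_abs_err = abs(trend_features$zero_crossing - tf[["crossing"]]),
      vertex_true = tf[["vertex"]], vertex_est = trend_features$vertex,
      vertex_abs_err = abs(trend_features$vertex - tf[["vertex"]])
    )
  }
  if (!is.null(importances)) {
    check_run(importances)
    out$driver_top <- importances$factor[which.max(importances$importance)]
  }
  out
}
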