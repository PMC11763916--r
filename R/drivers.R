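#' Daily extraterrestrial radiation
#'
#' Top-of-atmosphere daily solar radiation (MJ m^-2 d^-1) from latitude and
#' day of year via the standard sunset-hour-angle formula; the radiation input
#' to the Hargreaves PET estimate.
#'
#' @param latitude Degrees.
#' @param doy Day of year (1-366).
#' @return Radiation, MJ m^-2 d^-1.
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  gsc <- 0.0820 # MJ m-2 min-1
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  ws <- acos(x)
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Daily potential evapotranspiration (Hargreaves)
#'
#' Temperature-based PET: `0.0023 * Ra_mm * (Tmean + 17.8) * sqrt(Trange)`,
#' with the extraterrestrial radiation converted to evaporation-equivalent mm
#' (division by the latent heat 2.45 MJ kg^-1). Negative estimates are
#' truncated at zero.
#'
#' @param latitude Degrees.
#' @param doy Day of year.
#' @param tmean Daily mean air temperature, degrees C.
#' @param trange Daily temperature range (e.g. `ta_day - ta_night`), deg C;
#'   clamped below at 0.
#' @return PET in mm d^-1.
#' @export
pet_hargreaves <- function(latitude, doy, tmean, trange) {
  ra_mm <- extraterrestrial_radiation(latitude, doy) / 2.45
  pmax(0, 0.0023 * ra_mm * (tmean + 17.8) * sqrt(pmax(trange, 0)))
}

#' P/PET wetness index
#'
#' Annual precipitation divided by annual potential evapotranspiration. Sites
#' with `P/PET < 0.50` (jointly with soil water content below 10% where that
#' rule is applied) are classified as arid; the 0.50 boundary itself is not
#' arid.
#'
#' @param annual_precip Annual precipitation, mm.
#' @param annual_pet Annual PET, mm; must be positive.
#' @return The dimensionless wetness index.
#' @examples
#' wetness_index(400, 800) # 0.5: on the arid boundary, not arid
#' @export
wetness_index <- function(annual_precip, annual_pet) {
  if (any(annual_pet <= 0, na.rm = TRUE)) {
    abort("annual_pet must be positive.")
  }
  annual_precip / annual_pet
}

#' Assemble the nine-factor driver table
#'
#' Builds one row per site-day with exactly the nine candidate drivers of the
#' daily RATIO — day length, LAI, the day-night temperature difference, P,
#' SWC, CO2, the annual P/PET wetness index, VPD, and wind speed — plus the
#' RATIO as target. LAI is an annual site value joined to all site-days of
#' that site-year; the wetness index is computed per site-year from daily
#' precipitation and Hargreaves PET. Rows with a missing target are dropped.
#'
#' @param summaries Filtered site-day summaries (must include `ws`).
#' @param metadata Site metadata with `latitude`.
#' @param lai Either a tibble with `site_id` (+ optionally `year`) and `lai`,
#'   or `NULL` if `summaries` already carries an `lai` column.
#' @return A tibble with columns `site_id`, `date`, the nine factors and
#'   `ratio`.
#' @export
driver_table <- function(summaries, metadata, lai = NULL) {
  stop_if_missing_cols(summaries,
                       c("site_id", "date", "year", "ratio", "day_length",
                         "delta_t", "precip", "swc", "co2", "vpd", "ws",
                         "ta_day", "ta_night"),
                       "summaries")
  df <- left_join(summaries,
                  select(metadata, "site_id", "latitude"), by = "site_id")
  if (!is.null(lai)) {
    by <- intersect(c("site_id", "year"), names(lai))
    df <- left_join(df, lai, by = by)
  }
  if (!"lai" %in% names(df)) abort("No LAI available: supply `lai` or an lai column.")

  doy <- as.integer(format(df$date, "%j"))
  df$pet <- pet_hargreaves(df$latitude, doy,
                           (df$ta_day + df$ta_night) / 2,
                           df$ta_day - df$ta_night)
  wet <- df |>
    group_by(.data$site_id, .data$year) |>
    summarise(wetness_index = wetness_index(sum(.data$precip, na.rm = TRUE),
                                            max(sum(.data$pet, na.rm = TRUE), 1e-6)),
              .groups = "drop")
  df |>
    left_join(wet, by = c("site_id", "year")) |>
    filter(!is.na(.data$ratio)) |>
    select("site_id", "date", "day_length", "lai", "delta_t", "precip",
           "swc", "co2", "wetness_index", "vpd", "ws", ratio = "ratio")
}

DRIVER_FACTORS <- c("day_length", "lai", "delta_t", "precip", "swc", "co2",
                    "wetness_index", "vpd", "ws")

#' Screen contributors to the daily RATIO by random-forest importance
#'
#' Fits a random forest of the daily RATIO on the nine candidate factors and
#' returns each factor's importance (permutation importance by default),
#' normalized to sum to 1, with rank order. Deterministic given `seed`.
#'
#' @param table Driver table from [driver_table()] (>= 100 complete rows).
#' @param seed Integer seed.
#' @param type `"permutation"` (default) or `"impurity"`.
#' @param num_trees Forest size (default 500).
#' @param max_rows Cap on rows used for the forest; larger tables are
#'   subsampled deterministically (importance estimates stabilize well below
#'   this size while keeping the fit tractable).
#' @return Tibble `factor`, `importance` (normalized, non-negative), `rank`.
#' @export
screen_contributors <- function(table, seed = 1L,
                                type = c("permutation", "impurity"),
                                num_trees = 500, max_rows = 20000L) {
  type <- match.arg(type)
  stop_if_missing_cols(table, c(DRIVER_FACTORS, "ratio"), "driver table")
  df <- table[complete.cases(table[, c(DRIVER_FACTORS, "ratio")]),
              c(DRIVER_FACTORS, "ratio")]
  if (nrow(df) < 100) abort("Driver screening needs at least 100 complete rows.")
  if (nrow(df) > max_rows) {
    set.seed(child_seed(seed, 97L))
    df <- df[sample.int(nrow(df), max_rows), ]
  }
  constant <- vapply(df[DRIVER_FACTORS], function(x) sd(x) == 0, logical(1))
  if (any(constant)) {
    warn(paste0("Constant predictor(s), importance forced to 0: ",
                paste(DRIVER_FACTORS[constant], collapse = ", ")))
  }
  fit <- ranger::ranger(ratio ~ ., data = df, num.trees = num_trees,
                        importance = type, seed = seed, num.threads = 1)
  imp <- fit$variable.importance[DRIVER_FACTORS]
  imp[is.na(imp) | imp < 0] <- 0
  imp[constant] <- 0
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  out <- tibble(factor = DRIVER_FACTORS, importance = unname(imp)) |>
    arrange(dplyr::desc(.data$importance)) |>
    mutate(rank = dplyr::row_number())
  # out-of-bag R2 of the forest: how much of the RATIO the nine factors
  # explain at all (near zero when the target is independent of them)
  attr(out, "oob_r_squared") <- fit$r.squared
  out
}

#' Binned LAI-RATIO relationship
#'
#' Bins the daily RATIO by LAI and reports the per-bin mean and standard
#' deviation of the RATIO (the SD is the shaded envelope of the relationship)
#' plus a monotone-trend statistic: the Spearman correlation of bin means with
#' bin centers.
#'
#' @param lai,ratio Paired numeric vectors.
#' @param n_bins Number of LAI bins (default 20).
#' @return An `lai_ratio_curve` tibble (`lai_bin_center`, `mean_ratio`,
#'   `sd_ratio`, `count`) with a `monotone_trend` attribute.
#' @export
lai_ratio_curve <- function(lai, ratio, n_bins = 20) {
  if (length(lai) != length(ratio)) abort("lai and ratio must have equal length.")
  ok <- !is.na(lai) & !is.na(ratio)
  if (!any(ok)) abort("No complete (lai, ratio) pairs.")
  lai <- lai[ok]; ratio <- ratio[ok]
  rng <- range(lai)
  if (diff(rng) == 0) {
    out <- tibble(lai_bin_center = rng[1], mean_ratio = mean(ratio),
                  sd_ratio = if (length(ratio) >= 2) sd(ratio) else NA_real_,
                  count = length(ratio))
    return(structure(out, class = c("lai_ratio_curve", class(out)),
                     monotone_trend = NA_real_))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  b <- pmin(findInterval(lai, edges, rightmost.closed = TRUE), n_bins)
  out <- tibble(lai = lai, ratio = ratio, bin = b) |>
    group_by(.data$bin) |>
    summarise(mean_ratio = mean(.data$ratio),
              sd_ratio = if (dplyr::n() >= 2) sd(.data$ratio) else NA_real_,
              count = dplyr::n(), .groups = "drop") |>
    mutate(lai_bin_center = (edges[.data$bin] + edges[.data$bin + 1]) / 2) |>
    select("lai_bin_center", "mean_ratio", "sd_ratio", "count")
  trend <- if (nrow(out) >= 3) {
    suppressWarnings(cor(out$lai_bin_center, out$mean_ratio, method = "spearman"))
  } else NA_real_
  structure(out, class = c("lai_ratio_curve", class(out)),
            monotone_trend = trend)
}
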