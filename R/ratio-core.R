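#' Potential (top-of-atmosphere) shortwave radiation for a time of day
#'
#' Standard solar-geometry estimate: solar declination from day of year, hour
#' angle from local solar time, and the solar constant scaled by the sine of
#' solar elevation (clamped at zero below the horizon). Used both to label the
#' photosynthetic period and to shape synthetic diurnal LE profiles.
#'
#' @param latitude Degrees, in \[-90, 90\].
#' @param doy Day of year (1-366).
#' @param hour Local solar hour in \[0, 24).
#' @return Potential shortwave flux density, W m^-2 (0 at night).
#' @export
sw_in_potential <- function(latitude, doy, hour) {
  solar_constant <- 1361
  decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365.25)
  lat <- latitude * pi / 180
  hour_angle <- (hour - 12) * pi / 12
  sin_elev <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(hour_angle)
  pmax(0, solar_constant * sin_elev)
}

#' Label half-hourly records as photosynthetic (day) or non-photosynthetic (night)
#'
#' The photosynthetic period is defined by a daytime rule: `"swinpot"`
#' (default) labels a slot as day when potential incoming shortwave is
#' positive; `"swin20"` labels it as day when measured incoming shortwave
#' exceeds 20 W m^-2 (requires a `sw_in` column). The label is deterministic
#' given the rule.
#'
#' @param records Half-hourly tibble with an `sw_in_pot` (or `sw_in`) column.
#' @param method `"swinpot"` or `"swin20"`.
#' @return `records` with a logical `is_day` column appended.
#' @export
partition_day_night <- function(records, method = c("swinpot", "swin20")) {
  method <- match.arg(method)
  src <- switch(method, swinpot = "sw_in_pot", swin20 = "sw_in")
  if (!src %in% names(records)) {
    abort(paste0("Daytime rule '", method, "' requires column '", src,
                 "', which is absent."))
  }
  thr <- switch(method, swinpot = 0, swin20 = 20)
  mutate(records, is_day = !is.na(.data[[src]]) & .data[[src]] > thr)
}

#' Daily RATIO from labeled half-hourly LE values
#'
#' The daily RATIO is the daytime (photosynthetic-period) latent-heat-flux sum
#' divided by the whole-day sum. Negative values (nocturnal condensation,
#' instrument artifacts) are retained in both sums, so the raw ratio can fall
#' outside (0, 1); such days are removed later by [filter_ratio()].
#'
#' @param le Numeric vector of half-hourly LE values (W m^-2), `NA` allowed.
#' @param is_day Logical vector of the same length.
#' @return The ratio, or `NA` if the whole-day sum is zero or all LE missing.
#' @examples
#' compute_daily_ratio(c(8, 2), c(TRUE, FALSE)) # 0.8
#' @export
compute_daily_ratio <- function(le, is_day) {
  stopifnot(length(le) == length(is_day))
  total <- sum(le, na.rm = TRUE)
  if (all(is.na(le)) || total == 0) return(NA_real_)
  sum(le[is_day], na.rm = TRUE) / total
}

#' Aggregate labeled half-hourly records to site-day summaries
#'
#' Builds one row per site-day: the daily RATIO, day length (0.5 h per slot
#' labeled day), per-period air-temperature means (`ta_day`, `ta_night`),
#' daily means of VPD, Rn, CO2 and SWC, the daily precipitation sum, the daily
#' LE total in native energy units, per-period sums of NEE, RECO and GPP, the
#' day-night temperature difference `delta_t`, and the inherent water-use
#' efficiency `wuei_gpp = gpp_day * vpd / le_day`. Days whose fraction of
#' non-missing LE slots falls below `min_coverage` are marked invalid
#' (`valid = FALSE`) and their ratio set to `NA`.
#'
#' @param records Half-hourly tibble with `site_id`, `date`, `is_day` (from
#'   [partition_day_night()]) and the EC variable columns present.
#' @param min_coverage Minimum fraction of the 48 slots with non-missing LE
#'   for a day to be summarized as valid (default 0.9).
#' @return A tibble of site-day summaries (one row per site-day).
#' @export
summarize_daily <- function(records, min_coverage = 0.9) {
  stop_if_missing_cols(records, c("site_id", "date", "is_day", "le"),
                       "half-hourly records")
  has <- function(v) v %in% names(records)
  col <- function(v) if (has(v)) records[[v]] else rep(NA_real_, nrow(records))

  df <- tibble(
    site_id = records$site_id, date = records$date, is_day = records$is_day,
    le = records$le, ta = col("ta"), vpd = col("vpd"), rn = col("netrad"),
    precip = col("precip"), co2 = col("co2"), swc = col("swc"),
    nee = col("nee"), reco = col("reco"), gpp = col("gpp")
  )

  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sum_na  <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)

  out <- df |>
    group_by(.data$site_id, .data$date) |>
    summarise(
      # NOTE: summarise() exposes freshly created columns to later
      # expressions, so every per-period aggregate must be computed before
      # the whole-day column that reuses the same name.
      n_slots = dplyr::n(),
      coverage_fraction = mean(!is.na(.data$le)),
      day_length = 0.5 * sum(.data$is_day),
      ratio = compute_daily_ratio(.data$le, .data$is_day),
      le_day = sum_na(.data$le[.data$is_day]),
      ta_day = mean_na(.data$ta[.data$is_day]),
      ta_night = mean_na(.data$ta[!.data$is_day]),
      nee_day = sum_na(.data$nee[.data$is_day]),
      nee_night = sum_na(.data$nee[!.data$is_day]),
      reco_day = sum_na(.data$reco[.data$is_day]),
      reco_night = sum_na(.data$reco[!.data$is_day]),
      gpp_day = sum_na(.data$gpp[.data$is_day]),
      le = sum_na(.data$le),
      nee = sum_na(.data$nee),
      vpd = mean_na(.data$vpd),
      rn = mean_na(.data$rn),
      co2 = mean_na(.data$co2),
      swc = mean_na(.data$swc),
      precip = sum_na(.data$precip),
      .groups = "drop"
    ) |>
    mutate(
      delta_t = .data$ta_day - .data$ta_night,
      wuei_gpp = ifelse(!is.na(.data$le_day) & .data$le_day > 0,
                        .data$gpp_day * .data$vpd / .data$le_day, NA_real_),
      valid = .data$coverage_fraction >= min_coverage,
      ratio = ifelse(.data$valid, .data$ratio, NA_real_),
      year = as.integer(format(.data$date, "%Y"))
    )
  out
}

#' Apply the open-interval (0, 1) filter to daily RATIOs
#'
#' Physically the daytime share of a day's vapor flux must lie strictly
#' between 0 and 1; ratios outside that open interval (driven mostly by
#' negative nocturnal LE) are measurement artifacts and are discarded. The
#' discarded proportion is reported alongside the kept rows.
#'
#' @param summaries Tibble with a `ratio` column (site-day summaries).
#' @return A list with `kept` (tibble of rows with `0 < ratio < 1`),
#'   `discarded_fraction` (proportion of non-missing ratios removed), and
#'   `n_discarded`.
#' @examples
#' filter_ratio(tibble::tibble(ratio = c(0.5, 1.2, -0.1, 0.93)))$discarded_fraction
#' @export
filter_ratio <- function(summaries) {
  stop_if_missing_cols(summaries, "ratio", "summaries")
  has_ratio <- !is.na(summaries$ratio)
  ok <- has_ratio & summaries$ratio > 0 & summaries$ratio < 1
  n_eval <- sum(has_ratio)
  list(
    kept = summaries[ok, , drop = FALSE],
    discarded_fraction = if (n_eval == 0) NA_real_ else sum(has_ratio & !ok) / n_eval,
    n_discarded = sum(has_ratio & !ok)
  )
}

#' Aggregate site-day summaries to monthly or annual means
#'
#' The "mean daily RATIO" of a period is the arithmetic mean of the daily
#' ratio values within the period (not a ratio of period sums), matching the
#' per-day definition of the statistic. All other EC variables are averaged
#' the same way.
#'
#' @param summaries Filtered site-day summaries (ratios in (0, 1)).
#' @param scale `"annual"` or `"monthly"`.
#' @param by_site Keep sites separate (default `TRUE`); if `FALSE`, pool all
#'   sites within each period.
#' @return Tibble with the grouping columns, `n_days`, `ratio` (mean daily
#'   RATIO) and the mean of every EC variable present.
#' @export
aggregate_timescale <- function(summaries, scale = c("annual", "monthly"),
                                by_site = TRUE) {
  scale <- match.arg(scale)
  stop_if_missing_cols(summaries, c("site_id", "date", "ratio"), "summaries")
  g <- summaries |>
    mutate(year = as.integer(format(.data$date, "%Y")),
           month = as.integer(format(.data$date, "%m")))
  keys <- c(if (by_site) "site_id", "year", if (scale == "monthly") "month")
  vars <- intersect(c("ratio", "day_length", EC_VARS), names(g))
  g |>
    filter(!is.na(.data$ratio)) |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(n_days = dplyr::n(),
              across(dplyr::all_of(vars), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
}

#' Zonal mean daily RATIO summary
#'
#' Joins filtered site-day summaries with site metadata and reports, per
#' climate zone (and overall), the mean daily RATIO. The mean is taken over
#' site-level annual means so that long-running sites do not dominate.
#'
#' @param summaries Filtered site-day summaries.
#' @param metadata Site metadata from [read_site_metadata()].
#' @return Tibble with `climate_zone`, `n_sites`, `mean_ratio`.
#' @export
zone_ratio_summary <- function(summaries, metadata) {
  site_means <- summaries |>
    filter(!is.na(.data$ratio), .data$ratio > 0, .data$ratio < 1) |>
    group_by(.data$site_id) |>
    summarise(site_ratio = mean(.data$ratio), .groups = "drop") |>
    left_join(select(metadata, "site_id", "climate_zone"), by = "site_id")
  zones <- site_means |>
    group_by(.data$climate_zone) |>
    summarise(n_sites = dplyr::n(), mean_ratio = mean(.data$site_ratio),
              .groups = "drop")
  bind_rows(zones,
            tibble(climate_zone = "all", n_sites = nrow(site_means),
                   mean_ratio = mean(site_means$site_ratio)))
}
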