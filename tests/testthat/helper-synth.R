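# Small, fast generator configurations shared across test files.

# a handful of sites, one or two years, daily resolution
tiny_config <- function(seed = 101L, n_sites = 4, years = 2005:2006, ...) {
  synth_config(n_sites = n_sites,
               latitudes = seq(-45, 55, length.out = n_sites),
               years = years, seed = seed, ...)
}

tiny_sim <- function(seed = 101L, ...) {
  simulate_daily_summaries(tiny_config(seed = seed, ...))
}

# one site, a few days, half-hourly resolution
tiny_hh <- function(seed = 202L, latitudes = 10, years = 2005L, n_sites = 1) {
  simulate_half_hourly(synth_config(
    n_sites = n_sites, latitudes = latitudes, years = years, seed = seed))
}

# hand-built half-hourly records for one site-day with full control
manual_day <- function(le, is_day, date = as.Date("2005-06-01"),
                       site_id = "XX-Tst", ta = NULL) {
  n <- length(le)
  tibble::tibble(
    site_id = site_id,
    timestamp = as.POSIXct(date, tz = "UTC") + (seq_len(n) - 1) * 1800,
    date = date,
    le = le,
    ta = ta %||% rep(15, n),
    sw_in_pot = ifelse(is_day, 500, 0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
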