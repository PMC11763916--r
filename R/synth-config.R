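#' Default prescribed coupling curves between EC variables and the daily RATIO
#'
#' Builds the generator's ground-truth coupling functions. Flux and energy
#' variables follow a unimodal curve rising from a low value at RATIO 0 to a
#' peak at `peak` (default 0.94) and declining gently towards RATIO 1; NEE and
#' NEE-day are inverted (they decline to a minimum at the peak). The three
#' matter variables (P, CO2, SWC) decline approximately linearly with RATIO.
#' Values are daily aggregates in the same units the daily summarizer
#' produces: per-period sums for the carbon fluxes and LE, daily means for the
#' energy and matter variables, a daily sum for precipitation.
#'
#' The unimodal shape is the smooth sextic with derivative proportional to
#' `(peak - x) * (x + 0.05)^4`: it rises over the whole (0, peak) range with
#' an asymmetric shoulder and falls off by about 6% of its range between the
#' peak and RATIO 1 — the shape family binned flux data trace out.
#'
#' @param peak RATIO at which the unimodal curves turn over, in \[0.93, 0.95\].
#' @return Named list of functions of the daily RATIO, one per EC variable,
#'   with a `"ranges"` attribute holding each variable's (lo, hi) endpoints.
#' @export
default_couplings <- function(peak = 0.94) {
  stopifnot(peak > 0.5, peak < 1)
  ranges <- list(
    # energy variables: daily(-period) means
    ta_day   = c(2, 22),     # deg C
    ta_night = c(0, 16),     # deg C
    vpd      = c(2, 12),     # hPa
    rn       = c(40, 160),   # W m-2
    # flux variables: daily / per-period totals over the 48 half-hour slots
    le        = c(1000, 5500),  # W m-2 summed over slots
    nee       = c(50, -200),    # umol m-2 s-1 summed over slots
    nee_day   = c(0, -400),
    nee_night = c(25, 150),
    reco_night = c(25, 200),
    reco_day   = c(25, 225),
    gpp_day    = c(50, 600),
    wuei_gpp   = c(0.2, 1.5),
    # matter variables: daily mean (CO2, SWC) or daily sum (P)
    precip = c(6, 1),        # mm d-1
    co2    = c(410, 385),    # ppm
    swc    = c(35, 12)       # %
  )
  unimodal <- function(lo, hi, p) {
    force(lo); force(hi); force(p)
    a <- 0.05
    # antiderivative coefficients of (p - t) * (t + a)^4, powers x^1..x^6
    c4 <- choose(4, 0:4) * a^(4:0)            # (t + a)^4, powers t^0..t^4
    c5 <- c(p * c4, 0) - c(0, c4)             # * (p - t), powers t^0..t^5
    ci <- c5 / seq_len(6)                     # integrate, powers t^1..t^6
    u <- function(x) {
      xp <- outer(x, seq_len(6), `^`)
      drop(xp %*% ci)
    }
    top <- u(p)
    function(x) lo + (hi - lo) * u(x) / top
  }
  linear <- function(lo, hi) {
    force(lo); force(hi)
    function(x) lo + (hi - lo) * x
  }
  fns <- lapply(names(ranges), function(v) {
    r <- ranges[[v]]
    if (v %in% EC_MATTER_VARS) linear(r[1], r[2])
    else unimodal(r[1], r[2], peak)
  })
  names(fns) <- names(ranges)
  attr(fns, "ranges") <- ranges
  attr(fns, "peak") <- peak
  fns
}

#' Default prescribed temporal-trend profiles
#'
#' Ground-truth linear year coefficients (slope per year, in each variable's
#' own units) as a function of the daily RATIO. The default emulates the
#' signature regime structure of the daytime-air-temperature trend: the
#' profile crosses zero steeply at RATIO `crossing` (0.55), rises rapidly to
#' a plateau, climbs slowly to a well-defined vertex at `vertex` (0.90), and
#' declines at an accelerating pace beyond it. Atmospheric CO2 rises
#' everywhere at ~2 ppm per year; all other variables carry no trend (and
#' double as the zero-trend null).
#'
#' The Ta-day shape is piecewise: a linear ramp of slope `rise` (in
#' normalized profile units per unit RATIO) through zero at `crossing`,
#' capped at the `plateau` level, then a quadratic cap of half-width
#' `cap_width` peaking at `vertex`. The concentrated curvature at the vertex
#' is what makes the vertex of the resulting signed-trend curve localizable
#' from binned data.
#'
#' @param crossing RATIO where the Ta-day trend changes sign.
#' @param vertex RATIO where the Ta-day trend peaks.
#' @param ta_day_max Peak Ta-day slope, degrees C per year.
#' @param plateau Plateau level as a fraction of the peak slope.
#' @param rise Ramp steepness through the zero-crossing (profile units per
#'   unit RATIO).
#' @param cap_width Half-width of the quadratic cap around the vertex.
#' @return Named list of slope functions of the daily RATIO.
#' @export
default_trends <- function(crossing = 0.55, vertex = 0.90, ta_day_max = 0.05,
                           plateau = 0.4, rise = 8, cap_width = 0.10) {
  stopifnot(crossing < vertex - cap_width, plateau > 0, plateau < 1, rise > 0)
  ta_fun <- function(x) {
    ramp <- pmin(rise * (x - crossing), plateau)
    cap <- plateau + (1 - plateau) * (1 - ((x - vertex) / cap_width)^2)
    ta_day_max * ifelse(x >= vertex - cap_width, cap, ramp)
  }
  fns <- lapply(EC_VARS, function(v) function(x) rep(0, length(x)))
  names(fns) <- EC_VARS
  fns$ta_day <- ta_fun
  fns$co2 <- function(x) rep(2, length(x))
  attr(fns, "features") <- c(crossing = crossing, vertex = vertex)
  fns
}

#' Configuration of the synthetic flux-network generator
#'
#' Assembles the full parameterization of the generator: network layout,
#' years, prescribed RATIO couplings and temporal trends, noise magnitudes,
#' site random effects, the share of days engineered to yield out-of-range
#' ratios, and the LAI link that sets each site's mean daily RATIO.
#'
#' Defaults describe a 30-site network spanning 70 deg S to 70 deg N over the
#' 18 years 1997-2014, with observation noise of 10% of each coupling curve's
#' range for flux and energy variables and 40% for matter variables (their
#' couplings are the loosest), site offsets of 1.5% / 3% / 10% of range for
#' flux / energy / matter variables, and 23.4% of days perturbed to raw
#' ratios outside (0, 1) via negative nocturnal LE.
#'
#' @param n_sites Number of sites.
#' @param latitudes Per-site latitudes, degrees.
#' @param years Integer vector of calendar years.
#' @param couplings Coupling-function list, see [default_couplings()].
#' @param trends Trend-slope list, see [default_trends()].
#' @param noise_frac Named or scalar fractions of curve range used as
#'   observation noise SD; defaults per class as above.
#' @param site_effect_frac Same, for between-site offset SDs.
#' @param ratio_sd Within-site SD of the daily RATIO around the site mean.
#' @param target_out_of_range_fraction Share of days engineered to produce a
#'   raw ratio outside (0, 1).
#' @param lai_link Monotone function from site LAI to the site's mean daily
#'   RATIO.
#' @param runoff_fraction Share of daily precipitation routed to runoff in
#'   the water-balance closure.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sites = 30,
                         latitudes = seq(-70, 70, length.out = n_sites),
                         years = 1997:2014,
                         couplings = default_couplings(),
                         trends = default_trends(),
                         noise_frac = NULL,
                         site_effect_frac = NULL,
                         ratio_sd = 0.12,
                         target_out_of_range_fraction = 0.234,
                         lai_link = function(lai) 0.50 + 0.47 * lai / (lai + 1),
                         runoff_fraction = 0.4,
                         seed = 1L) {
  stopifnot(n_sites >= 1, length(latitudes) == n_sites,
            all(abs(latitudes) <= 90), length(years) >= 1,
            ratio_sd > 0,
            target_out_of_range_fraction >= 0,
            target_out_of_range_fraction < 1,
            runoff_fraction >= 0, runoff_fraction < 1)

  class_frac <- function(flux, energy, matter) {
    f <- setNames(numeric(length(EC_VARS)), EC_VARS)
    f[EC_FLUX_VARS] <- flux; f[EC_ENERGY_VARS] <- energy
    f[EC_MATTER_VARS] <- matter
    f
  }
  default_noise <- class_frac(0.10, 0.10, 0.40)
  default_site  <- class_frac(0.015, 0.03, 0.10)
  if (is.null(noise_frac)) noise_frac <- default_noise
  if (length(noise_frac) == 1 && is.null(names(noise_frac))) {
    noise_frac <- setNames(rep(noise_frac, length(EC_VARS)), EC_VARS)
  }
  if (is.null(site_effect_frac)) site_effect_frac <- default_site
  if (length(site_effect_frac) == 1 && is.null(names(site_effect_frac))) {
    site_effect_frac <- setNames(rep(site_effect_frac, length(EC_VARS)), EC_VARS)
  }

  ranges <- attr(couplings, "ranges")
  span <- vapply(ranges[EC_VARS], function(r) abs(diff(r)), numeric(1))
  structure(list(
    n_sites = as.integer(n_sites),
    latitudes = latitudes,
    years = as.integer(years),
    couplings = couplings,
    trends = trends,
    noise_sd = noise_frac[EC_VARS] * span,
    site_effect_sd = site_effect_frac[EC_VARS] * span,
    ratio_sd = ratio_sd,
    target_out_of_range_fraction = target_out_of_range_fraction,
    lai_link = lai_link,
    runoff_fraction = runoff_fraction,
    latent_heat_mm_per_unit = 0.5 * 1800 / 2.45e6,  # W m-2 half-hour slot -> mm water
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat("  sites:", x$n_sites, " years:", min(x$years), "-", max(x$years), "\n")
  cat("  out-of-range day fraction:", x$target_out_of_range_fraction, "\n")
  cat("  ratio_sd:", x$ratio_sd, " seed:", x$seed, "\n")
  invisible(x)
}

# Site-level layout shared by the daily and half-hourly generators:
# coordinates, land cover, LAI (scrambled across latitude so vegetation and
# climate zone are not confounded), site mean RATIO from the LAI link, and
# per-variable site offsets.
synth_sites <- function(config) {
  n <- config$n_sites
  set.seed(child_seed(config$seed, 0L))
  igbp_cycle <- c("ENF", "DBF", "GRA", "CRO", "EBF", "WSA",
                  "WET", "OSH", "MF", "SAV")
  perm <- ((seq_len(n) - 1) * 17L) %% n + 1L
  lai_sorted <- exp(seq(log(0.2), log(6), length.out = n))
  lai <- lai_sorted[perm]
  meta <- tibble(
    site_id = sprintf("SY-%03d", seq_len(n)),
    latitude = config$latitudes,
    longitude = ifelse(seq_len(n) %% 2 == 0, 100 - seq_len(n), -100 + seq_len(n)),
    igbp_class = rep_len(igbp_cycle, n),
    lai = lai,
    mean_ratio = config$lai_link(lai)
  ) |>
    mutate(climate_zone = climate_zone(.data$latitude),
           group = igbp_group(.data$igbp_class),
           hemisphere = ifelse(.data$longitude >= 0, "eastern", "western"))
  offsets <- vapply(EC_VARS, function(v) rnorm(n, 0, config$site_effect_sd[[v]]),
                    numeric(n))
  if (n == 1) offsets <- matrix(offsets, nrow = 1,
                                dimnames = list(NULL, EC_VARS))
  ws_base <- pmax(0.5, rnorm(n, 3, 0.8))
  list(metadata = meta, offsets = offsets, ws_base = ws_base)
}
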