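#' Critical correlation coefficient for a linear temporal trend
#'
#' Two-sided significance threshold for a Pearson correlation based on `n`
#' points: `t_crit / sqrt(t_crit^2 + n - 2)` with `t_crit` the two-sided
#' t quantile at level `alpha` on `n - 2` degrees of freedom. For the 18 years
#' 1997-2014 at `alpha = 0.05` this is 0.47 (2 dp) — the significance band of
#' the trend curves.
#'
#' @param n_points Number of points in the regression (e.g. years).
#' @param alpha Two-sided significance level (default 0.05).
#' @return The critical |r| threshold in (0, 1).
#' @examples
#' round(critical_r(18), 2) # 0.47
#' @export
critical_r <- function(n_points, alpha = 0.05) {
  if (any(n_points < 3)) abort("critical_r() needs n_points >= 3.")
  stopifnot(alpha > 0, alpha < 1)
  tc <- qt(1 - alpha / 2, df = n_points - 2)
  tc / sqrt(tc^2 + n_points - 2)
}

#' Signed trend coefficient from slope and R-squared
#'
#' The temporal trend of a variable is expressed as `r = +/- sqrt(R^2)`, the
#' Pearson correlation with calendar year signed by the regression slope.
#'
#' @param slope Regression slope(s).
#' @param r_squared Fit R-squared value(s) in \[0, 1\].
#' @return `sign(slope) * sqrt(r_squared)`; 0 where the slope is 0.
#' @examples
#' signed_r(2, 0.25)  # 0.5
#' @export
signed_r <- function(slope, r_squared) {
  if (any(r_squared < 0 | r_squared > 1, na.rm = TRUE)) {
    abort("r_squared must lie in [0, 1].")
  }
  sign(slope) * sqrt(r_squared)
}

#' Bootstrap specification for the trend curves
#'
#' @param n_bins Number of RATIO sub-intervals (default 50).
#' @param B Number of bootstrap samples per bin (default 1000).
#' @param sample_size Records drawn (with replacement) per sample (default
#'   4000).
#' @param min_unique_sites Least number of distinct sites that must appear in
#'   each sample (default 10); samples are redrawn (up to `max_redraws`) until
#'   satisfied.
#' @param alpha Two-sided significance level for the critical-r band.
#' @param seed Integer seed; per-bin seeds are derived from it so each bin is
#'   independently reproducible.
#' @param unit `"annual_means"` (default) regresses the sample's annual means
#'   on year — the unit under which the critical band `r = 0.47` for 18 years
#'   applies; `"records"` regresses raw records on year.
#' @param max_redraws Redraw cap per sample before the sample is skipped.
#' @return A `bootstrap_spec` list.
#' @export
bootstrap_spec <- function(n_bins = 50, B = 1000, sample_size = 4000,
                           min_unique_sites = 10, alpha = 0.05, seed = 1L,
                           unit = c("annual_means", "records"),
                           max_redraws = 100) {
  unit <- match.arg(unit)
  stopifnot(n_bins >= 2, B >= 1, sample_size >= min_unique_sites,
            min_unique_sites >= 1, alpha > 0, alpha < 1)
  structure(list(n_bins = as.integer(n_bins), B = as.integer(B),
                 sample_size = as.integer(sample_size),
                 min_unique_sites = as.integer(min_unique_sites),
                 alpha = alpha, seed = as.integer(seed), unit = unit,
                 max_redraws = as.integer(max_redraws)),
            class = "bootstrap_spec")
}

# Fast Pearson correlation of y with x (equals sign(slope) * sqrt(R^2) for a
# simple linear regression).
fast_cor <- function(x, y) {
  sx <- sd(x); sy <- sd(y)
  if (is.na(sx) || is.na(sy) || sx == 0 || sy == 0) return(NA_real_)
  cor(x, y)
}

#' Bootstrap distribution of temporal-trend coefficients per RATIO sub-interval
#'
#' Divides the RATIO range into `spec$n_bins` sub-intervals; within each bin
#' with records from at least `min_unique_sites` distinct sites, draws `B`
#' bootstrap samples of `sample_size` records (with replacement, redrawing
#' until the distinct-site constraint holds), regresses the variable on
#' calendar year within each sample, and stores the signed trend coefficient
#' `r = sign(slope) * sqrt(R^2)`. With the default `"annual_means"` unit each
#' sample is first collapsed to one mean per year, so `r` is comparable to the
#' [critical_r()] band for the number of observed years. Records are put in a
#' canonical (site, date) order first, making the result invariant to input
#' row order; per-bin seeds derive from `spec$seed`.
#'
#' @param summaries Filtered site-day summaries spanning >= 3 distinct years.
#' @param variable EC variable to analyse.
#' @param spec A [bootstrap_spec()].
#' @return A `trend_curve` list: `variable`, `bin_centers`, `r_samples`
#'   (matrix, B x populated bins), `summary` tibble (per-bin median and
#'   quantiles of r, significant fractions), `critical_r`, `n_years`, `spec`,
#'   and `skipped_bins`.
#' @export
bootstrap_trends <- function(summaries, variable, spec = bootstrap_spec()) {
  stop_if_missing_cols(summaries, c("site_id", "date", "year", "ratio", variable),
                       "summaries")
  if (any(summaries$ratio <= 0 | summaries$ratio >= 1, na.rm = TRUE)) {
    abort("summaries contain ratios outside (0, 1); run filter_ratio() first.")
  }
  df <- summaries |>
    filter(!is.na(.data$ratio), !is.na(.data[[variable]])) |>
    arrange(.data$site_id, .data$date)
  years <- sort(unique(df$year))
  if (length(years) < 3) abort("Need summaries spanning at least 3 distinct years.")
  crit <- critical_r(length(years), spec$alpha)

  edges <- seq(0, 1, length.out = spec$n_bins + 1)
  bin <- pmin(findInterval(df$ratio, edges, rightmost.closed = TRUE), spec$n_bins)
  site_code <- as.integer(factor(df$site_id))
  year_idx <- match(df$year, years)
  value <- df[[variable]]

  populated <- sort(unique(bin))
  keep <- logical(length(populated))
  r_cols <- vector("list", length(populated))
  skipped <- integer(0)

  for (k in seq_along(populated)) {
    b <- populated[k]
    idx_bin <- which(bin == b)
    if (length(unique(site_code[idx_bin])) < spec$min_unique_sites) {
      skipped <- c(skipped, b)
      next
    }
    v_b <- value[idx_bin]
    s_b <- site_code[idx_bin]
    y_b <- year_idx[idx_bin]
    n_b <- length(idx_bin)
    set.seed(child_seed(spec$seed, b))
    r_vec <- rep(NA_real_, spec$B)
    for (s in seq_len(spec$B)) {
      draws <- 0L
      repeat {
        take <- sample.int(n_b, spec$sample_size, replace = TRUE)
        draws <- draws + 1L
        if (length(unique(s_b[take])) >= spec$min_unique_sites) break
        if (draws >= spec$max_redraws) {
          take <- NULL
          break
        }
      }
      if (is.null(take)) next
      if (spec$unit == "annual_means") {
        cnt <- tabulate(y_b[take], nbins = length(years))
        pres <- which(cnt > 0)
        if (length(pres) < 3) next
        sums <- rowsum(v_b[take], y_b[take], reorder = TRUE)
        r_vec[s] <- fast_cor(years[pres], as.vector(sums) / cnt[pres])
      } else {
        r_vec[s] <- fast_cor(years[y_b[take]], v_b[take])
      }
    }
    keep[k] <- TRUE
    r_cols[[k]] <- r_vec
  }
  if (!any(keep)) abort("No bin satisfies the unique-site constraint; empty trend curve.")
  populated <- populated[keep]
  r_mat <- do.call(cbind, r_cols[keep])
  centers <- (edges[populated] + edges[populated + 1]) / 2
  colnames(r_mat) <- sprintf("bin_%03d", populated)
  if (length(skipped) > 0) {
    inform(paste0(length(skipped),
                  " bin(s) skipped for having fewer than ",
                  spec$min_unique_sites, " distinct sites."))
  }

  summ <- tibble(
    bin = populated,
    bin_center = centers,
    r_median = apply(r_mat, 2, median, na.rm = TRUE),
    r_q05 = apply(r_mat, 2, quantile, probs = 0.05, na.rm = TRUE),
    r_q25 = apply(r_mat, 2, quantile, probs = 0.25, na.rm = TRUE),
    r_q75 = apply(r_mat, 2, quantile, probs = 0.75, na.rm = TRUE),
    r_q95 = apply(r_mat, 2, quantile, probs = 0.95, na.rm = TRUE),
    frac_sig_pos = apply(r_mat, 2, function(r) mean(r > crit, na.rm = TRUE)),
    frac_sig_neg = apply(r_mat, 2, function(r) mean(r < -crit, na.rm = TRUE)),
    n_records = as.vector(table(factor(bin, levels = populated)))
  )
  structure(list(variable = variable, bin_centers = centers,
                 r_samples = r_mat, summary = summ, critical_r = crit,
                 n_years = length(years), spec = spec,
                 skipped_bins = skipped),
            class = "trend_curve")
}

#' @export
print.trend_curve <- function(x, ...) {
  cat("<trend_curve>", x$variable, "over", length(x$bin_centers),
      "populated RATIO bins\n")
  cat("  B =", x$spec$B, " sample size =", x$spec$sample_size,
      " critical |r| =", round(x$critical_r, 3), "\n")
  invisible(x)
}

#' @rdname bootstrap_trends
#' @param x,object A `trend_curve`.
#' @param ... Unused.
#' @export
tidy.trend_curve <- function(x, ...) x$summary

#' @rdname bootstrap_trends
#' @export
glance.trend_curve <- function(x, ...) {
  f <- curve_features(x)
  tibble(variable = x$variable, n_bins = length(x$bin_centers),
         critical_r = x$critical_r, n_years = x$n_years,
         zero_crossing = f$zero_crossing %||% NA_real_,
         vertex = f$vertex)
}

#' Features of a trend curve: zero-crossings, vertex, slope regimes
#'
#' Summarises the per-bin bootstrap distributions with a central statistic
#' (default: median) and reads off where the summary curve crosses zero,
#' where it peaks (the vertex), and where its first difference changes the
#' most (descriptive slope-regime breakpoints).
#'
#' Because each bin's summary carries the sampling noise of a
#' few-points-per-regression correlation, the headline features are estimated
#' with light local pooling rather than from single bins: the reported
#' `zero_crossing` interpolates the sign change of a centered 3-bin moving
#' average and is then refined by an iterated local linear fit (on the
#' variance-stabilizing `atanh` scale) over the bins within 0.06 RATIO of the
#' running estimate, and the `vertex` is the stationary point of a local quadratic
#' fitted (on the variance-stabilizing `atanh` scale) to the bins within
#' 0.12 RATIO of the running argmax, iterated twice. The raw single-bin
#' readings (`all_crossings` by adjacent-bin interpolation, `vertex_raw` as
#' the raw argmax) are reported alongside.
#'
#' @param curve A `trend_curve` from [bootstrap_trends()], or any tibble with
#'   `bin_center` and an `r_median` column.
#' @param statistic Per-bin summary function (default [stats::median]).
#' @return A `trend_features` list: `zero_crossing`, `all_crossings` (raw),
#'   `vertex`, `vertex_raw`, `breakpoints` (RATIOs of the two largest changes
#'   in the first difference), and `statistic_curve`.
#' @export
curve_features <- function(curve, statistic = median) {
  if (inherits(curve, "trend_curve")) {
    x <- curve$bin_centers
    y <- apply(curve$r_samples, 2, statistic, na.rm = TRUE)
  } else {
    stop_if_missing_cols(curve, c("bin_center", "r_median"), "curve")
    x <- curve$bin_center
    y <- curve$r_median
  }
  if (length(x) < 5) abort("curve_features() needs at least 5 populated bins.")
  o <- order(x); x <- x[o]; y <- y[o]

  interp_crossings <- function(xx, yy) {
    sgn <- sign(yy)
    ok <- which(sgn[-length(sgn)] * sgn[-1] < 0)
    cr <- vapply(ok, function(i) {
      xx[i] - yy[i] * (xx[i + 1] - xx[i]) / (yy[i + 1] - yy[i])
    }, numeric(1))
    sort(unique(c(cr, xx[yy == 0])))
  }
  raw_crossings <- interp_crossings(x, y)

  ys <- as.vector(stats::filter(y, rep(1 / 3, 3)))
  keep <- !is.na(ys)
  smooth_crossings <- interp_crossings(x[keep], ys[keep])
  zero_crossing <- if (length(smooth_crossings) > 0) smooth_crossings[1] else
    if (length(raw_crossings) > 0) raw_crossings[1] else NULL

  z <- ifelse(abs(y) < 1, atanh(pmin(pmax(y, -0.999), 0.999)), y)

  # refine the crossing with an iterated local linear fit on the atanh scale
  if (!is.null(zero_crossing)) {
    cr <- zero_crossing
    for (it in 1:3) {
      w <- which(abs(x - cr) <= 0.06 + 1e-9)
      if (length(w) >= 4) {
        co <- coef(lm(z[w] ~ x[w]))
        if (is.finite(co[2]) && co[2] > 0) cr <- unname(-co[1] / co[2])
      }
    }
    if (cr >= min(x) && cr <= max(x)) zero_crossing <- cr
  }

  # vertex: iterated local quadratic on the atanh scale
  vertex <- x[which.max(z)]
  for (it in 1:2) {
    w <- which(abs(x - vertex) <= 0.12 + 1e-9)
    if (length(w) < 5) w <- order(abs(x - vertex))[seq_len(min(7, length(x)))]
    fit <- lm(z[w] ~ poly(x[w], 2, raw = TRUE))
    co <- coef(fit)
    if (is.finite(co[3]) && co[3] < 0) {
      v <- unname(-co[2] / (2 * co[3]))
      vertex <- min(max(v, min(x[w])), max(x[w]))
    }
  }

  d1 <- diff(y) / diff(x)
  d2 <- abs(diff(d1))
  mid <- x[-c(1, length(x))]
  bp <- if (length(d2) >= 2) mid[order(d2, decreasing = TRUE)[1:2]] else mid

  structure(list(
    zero_crossing = zero_crossing,
    all_crossings = raw_crossings,
    vertex = vertex,
    vertex_raw = x[which.max(y)],
    breakpoints = sort(bp),
    statistic_curve = tibble(bin_center = x, statistic = y)
  ), class = "trend_features")
}

#' @export
print.trend_features <- function(x, ...) {
  cat("<trend_features>\n")
  cat("  zero crossing:", if (is.null(x$zero_crossing)) "none" else
    round(x$zero_crossing, 3), "\n")
  cat("  vertex:", round(x$vertex, 3), "\n")
  cat("  slope breakpoints:", paste(round(x$breakpoints, 3), collapse = ", "), "\n")
  invisible(x)
}
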