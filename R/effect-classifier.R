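#' Rule table mapping RATIO regimes to greening temperature effects
#'
#' The regimes come from the Ta-day trend curve: its signed trend coefficient
#' rises steeply between RATIO 0.55 and 0.75 (greening warms strongly — and
#' below 0.55 the same positive local slope applies even though the trend
#' itself is negative), rises only slightly between 0.75 and 0.90 (weak
#' warming), and declines at an accelerating pace above 0.90 (cooling).
#' Intervals are half-open `[lower, upper)`, so 0.75 falls in the weak-warming
#' regime and 0.90 in the cooling regime. An optional two-level cooling split
#' at 0.93 separates weak cooling (0.90-0.93) from strong cooling (>= 0.93).
#'
#' @param two_level_cooling Split the cooling regime at 0.93 (default `FALSE`).
#' @return Tibble `lower`, `upper`, `greening_effect`, `rationale`.
#' @export
effect_rules <- function(two_level_cooling = FALSE) {
  base <- tibble(
    lower = c(0, 0.55, 0.75),
    upper = c(0.55, 0.75, 0.90),
    greening_effect = c("strong warming", "strong warming", "weak warming"),
    rationale = c(
      "Ta-day trend negative but rising steeply with RATIO",
      "Ta-day trend rises rapidly over 0.55-0.75",
      "Ta-day trend rises very slowly over 0.75-0.90 (minimal effect)"
    )
  )
  cooling <- if (two_level_cooling) {
    tibble(lower = c(0.90, 0.93), upper = c(0.93, 1),
           greening_effect = c("weak cooling", "strong cooling"),
           rationale = c("Ta-day trend declining just past the vertex",
                         "Ta-day trend in accelerating decline above 0.93"))
  } else {
    tibble(lower = 0.90, upper = 1, greening_effect = "strong cooling",
           rationale = "Ta-day trend declines at an accelerating pace above 0.90")
  }
  bind_rows(base, cooling)
}

flip_effect <- function(effect) {
  map <- c("strong warming" = "strong cooling",
           "weak warming"   = "weak cooling",
           "weak cooling"   = "weak warming",
           "strong cooling" = "strong warming",
           "no predicted change" = "no predicted change")
  unname(map[effect])
}

#' Classify the surface-temperature effect of a vegetation change
#'
#' Looks up the mean daily RATIO in the regime rule table and returns the
#' predicted Ta-day effect of the stated vegetation change. Browning returns
#' the sign-flipped greening label; `change_sign = "none"` predicts no change.
#'
#' @param mean_ratio Mean daily RATIO(s), strictly in (0, 1).
#' @param change_sign `"greening"`, `"browning"`, or `"none"` (recycled).
#' @param rules Rule table from [effect_rules()].
#' @return An `effect_label` tibble: `mean_ratio`, `change_sign`, `effect`,
#'   `rule_interval`, `rationale`.
#' @examples
#' classify_effect(c(0.94, 0.85, 0.73), "greening")
#' @export
classify_effect <- function(mean_ratio, change_sign = "greening",
                            rules = effect_rules()) {
  if (any(mean_ratio <= 0 | mean_ratio >= 1, na.rm = TRUE)) {
    abort("mean_ratio must lie strictly in (0, 1).")
  }
  change_sign <- rep_len(change_sign, length(mean_ratio))
  if (!all(change_sign %in% c("greening", "browning", "none"))) {
    abort("change_sign must be 'greening', 'browning' or 'none'.")
  }
  idx <- findInterval(mean_ratio, c(rules$lower, 1))
  idx <- pmin(idx, nrow(rules))
  effect <- rules$greening_effect[idx]
  effect[change_sign == "browning"] <- flip_effect(effect[change_sign == "browning"])
  effect[change_sign == "none"] <- "no predicted change"
  out <- tibble(
    mean_ratio = mean_ratio,
    change_sign = change_sign,
    effect = effect,
    rule_interval = sprintf("[%.2f, %.2f)", rules$lower[idx], rules$upper[idx]),
    rationale = rules$rationale[idx]
  )
  structure(out, class = c("effect_label", class(out)))
}

#' Classify the temperature effect from a fitted Ta-day trend curve
#'
#' Data-driven variant of [classify_effect()]: the effect's sign is the sign
#' of the trend curve's local derivative at the queried RATIO (positive slope
#' means an increase in RATIO — greening — warms) combined with the change
#' sign; the strength label comes from terciles of the curve's absolute
#' derivative. At the vertex (derivative near zero within the lowest decile
#' of |derivative|) the effect is "~ no change" and flagged. If the curve is
#' too noisy (more than `max_crossings` sign changes of the median r), the
#' static rule table is used instead and the result flagged.
#'
#' @param curve A Ta-day `trend_curve`.
#' @param mean_ratio Query RATIO(s), inside the populated bin range.
#' @param change_sign `"greening"` or `"browning"`.
#' @param max_crossings Noise guard on the median-r curve (default 3).
#' @return An `effect_label` tibble with an extra `flag` column.
#' @export
classify_from_trend_curve <- function(curve, mean_ratio,
                                      change_sign = "greening",
                                      max_crossings = 3) {
  stopifnot(inherits(curve, "trend_curve"))
  change_sign <- match.arg(change_sign, c("greening", "browning"))
  x <- curve$bin_centers
  y <- apply(curve$r_samples, 2, median, na.rm = TRUE)
  if (any(mean_ratio < min(x) | mean_ratio > max(x))) {
    abort("mean_ratio outside the populated bin range; cannot extrapolate.")
  }
  feats <- curve_features(curve)
  if (length(feats$all_crossings) > max_crossings) {
    warn("Trend curve too noisy; falling back to the static rule table.")
    out <- classify_effect(mean_ratio, change_sign)
    out$flag <- "static fallback (noisy curve)"
    return(out)
  }
  # centered first-derivative estimate on the bin grid
  d_grid <- (y[pmin(seq_along(y) + 1, length(y))] -
             y[pmax(seq_along(y) - 1, 1)]) /
            (x[pmin(seq_along(x) + 1, length(x))] -
             x[pmax(seq_along(x) - 1, 1)])
  deriv <- stats::approx(x, d_grid, xout = mean_ratio, rule = 2)$y
  terciles <- quantile(abs(d_grid), c(1/3, 2/3))
  near_zero <- abs(deriv) <= quantile(abs(d_grid), 0.1)

  sign_eff <- sign(deriv) * ifelse(change_sign == "greening", 1, -1)
  strength <- ifelse(abs(deriv) >= terciles[2], "strong",
                     ifelse(abs(deriv) >= terciles[1], "moderate", "weak"))
  effect <- ifelse(near_zero, "~ no change",
                   paste(strength, ifelse(sign_eff > 0, "warming", "cooling")))
  out <- tibble(
    mean_ratio = mean_ratio, change_sign = change_sign, effect = effect,
    rule_interval = NA_character_,
    rationale = sprintf("local d(r)/d(RATIO) = %.2f at RATIO %.2f",
                        deriv, mean_ratio),
    flag = ifelse(near_zero, "at/near vertex: derivative ~ 0", NA_character_)
  )
  structure(out, class = c("effect_label", class(out)))
}
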