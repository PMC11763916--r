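#' Bin site-day summaries by the daily RATIO
#'
#' Divides the RATIO range (0, 1) into `n_bins` equal sub-intervals and
#' averages one EC variable within each, optionally per group. Bins are
#' half-open `[edge_k, edge_{k+1})` with the last bin closed, so a value on an
#' interior edge belongs to the bin on its right.
#'
#' @param summaries Filtered site-day summaries (`0 < ratio < 1`).
#' @param variable Name of the EC variable column to bin.
#' @param n_bins Number of sub-intervals (default 200).
#' @param group_by Optional name of a grouping column in `summaries` (e.g.
#'   `"group"` or `"hemisphere"`); `NULL` pools everything.
#' @return A `binned_series` tibble with `group`, `bin`, `bin_center`,
#'   `bin_mean`, `bin_sd`, `bin_count` (only populated bins are kept).
#' @examples
#' s <- tibble::tibble(ratio = c(0.1, 0.1, 0.9), gpp_day = c(2, 4, 10))
#' bin_by_ratio(s, "gpp_day", n_bins = 2)
#' @export
bin_by_ratio <- function(summaries, variable, n_bins = 200, group_by = NULL) {
  if (n_bins < 2) abort("n_bins must be at least 2.")
  stop_if_missing_cols(summaries, c("ratio", variable, group_by), "summaries")
  if (any(summaries$ratio <= 0 | summaries$ratio >= 1, na.rm = TRUE)) {
    abort("summaries contain ratios outside (0, 1); run filter_ratio() first.")
  }
  edges <- seq(0, 1, length.out = n_bins + 1)
  df <- summaries |>
    filter(!is.na(.data$ratio), !is.na(.data[[variable]])) |>
    mutate(
      bin = pmin(findInterval(.data$ratio, edges, rightmost.closed = TRUE),
                 n_bins),
      group = if (is.null(group_by)) "all" else as.character(.data[[group_by]])
    )
  out <- df |>
    group_by(.data$group, .data$bin) |>
    summarise(bin_mean = mean(.data[[variable]]),
              bin_sd = sd(.data[[variable]]),
              bin_count = dplyr::n(), .groups = "drop") |>
    mutate(bin_center = (edges[.data$bin] + edges[.data$bin + 1]) / 2) |>
    select("group", "bin", "bin_center", "bin_mean", "bin_sd", "bin_count") |>
    arrange(.data$group, .data$bin)
  structure(out, class = c("binned_series", class(out)),
            variable = variable, n_bins = n_bins, edges = edges)
}

#' Fit a coupling curve of an EC variable against the daily RATIO
#'
#' Fits the relationship between a binned EC variable and the daily RATIO on
#' the (bin center, bin mean) pairs, weighted by bin counts. Two families are
#' supported: a raw polynomial (default degree 6, fitted by weighted least
#' squares) and a random forest (ranger, 500 trees, fixed seed for exact
#' reproducibility). Empty bins are skipped, never interpolated.
#'
#' @param binned A single-group `binned_series` from [bin_by_ratio()] (if it
#'   holds several groups, pass `group` to pick one).
#' @param family `"polynomial"` or `"random_forest"`.
#' @param degree Polynomial degree (default 6).
#' @param num_trees Random-forest size (default 500).
#' @param seed Integer seed for the forest fit.
#' @param group Which group to fit when `binned` has several.
#' @return A `coupling_model` with elements `variable`, `group`, `family`,
#'   `fit` (the lm or ranger object), `fit_domain` (RATIO interval covered by
#'   populated bins), `goodness` (weighted R-squared on training bins) and
#'   `n_bins_used`.
#' @export
fit_coupling_curve <- function(binned, family = c("polynomial", "random_forest"),
                               degree = 6, num_trees = 500, seed = 1L,
                               group = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(binned, "binned_series"))
  variable <- attr(binned, "variable")
  groups <- unique(binned$group)
  if (is.null(group)) {
    if (length(groups) > 1) {
      abort("binned series holds several groups; pass `group` to select one.")
    }
    group <- groups
  }
  df <- filter(as_tibble(binned), .data$group == .env$group)
  min_bins <- max(degree + 1, 5)
  if (nrow(df) < min_bins) {
    abort(paste0("Too few populated bins (", nrow(df), ") to fit; need >= ",
                 min_bins, "."))
  }

  if (family == "polynomial") {
    fit <- lm(bin_mean ~ poly(bin_center, degree, raw = TRUE),
              data = df, weights = df$bin_count)
    pred <- unname(fitted(fit))
  } else {
    set.seed(seed)
    fit <- ranger::ranger(
      bin_mean ~ bin_center, data = df[, c("bin_center", "bin_mean")],
      num.trees = num_trees, case.weights = df$bin_count,
      min.node.size = 2, seed = seed
    )
    pred <- predict(fit, data = df[, "bin_center", drop = FALSE])$predictions
  }
  w <- df$bin_count
  ss_res <- sum(w * (df$bin_mean - pred)^2)
  ss_tot <- sum(w * (df$bin_mean - stats::weighted.mean(df$bin_mean, w))^2)
  structure(list(
    variable = variable, group = group, family = family,
    degree = if (family == "polynomial") degree else NA_integer_,
    fit = fit,
    fit_domain = range(df$bin_center),
    goodness = 1 - ss_res / ss_tot,
    n_bins_used = nrow(df),
    seed = seed
  ), class = "coupling_model")
}

#' @export
predict.coupling_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$ratio %||% newdata$bin_center else newdata
  if (object$family == "polynomial") {
    unname(predict(object$fit, tibble(bin_center = x)))
  } else {
    predict(object$fit, data = tibble(bin_center = x))$predictions
  }
}

#' @export
print.coupling_model <- function(x, ...) {
  cat("<coupling_model>", x$variable, "~ daily RATIO |", x$group, "\n")
  cat("  family:", x$family,
      if (x$family == "polynomial") paste0("(degree ", x$degree, ")") else "",
      "\n")
  cat("  fit domain: [", round(x$fit_domain[1], 3), ",",
      round(x$fit_domain[2], 3), "]  R2 =", round(x$goodness, 4),
      " bins =", x$n_bins_used, "\n")
  invisible(x)
}

#' @rdname fit_coupling_curve
#' @param x,object A `coupling_model`.
#' @param ... Unused.
#' @export
tidy.coupling_model <- function(x, ...) {
  if (x$family == "polynomial") {
    co <- coef(x$fit)
    tibble(term = paste0("ratio^", seq_along(co) - 1), estimate = unname(co))
  } else {
    tibble(term = "num.trees", estimate = x$fit$num.trees)
  }
}

#' @rdname fit_coupling_curve
#' @export
glance.coupling_model <- function(x, ...) {
  tibble(variable = x$variable, group = x$group, family = x$family,
         r.squared = x$goodness, n_bins = x$n_bins_used,
         domain_lo = x$fit_domain[1], domain_hi = x$fit_domain[2])
}

#' Locate the extremum of a fitted coupling curve
#'
#' Evaluates the model on a RATIO grid and returns the location of the
#' maximum (minimum for NEE-type variables, which decline to a trough near
#' the turning point). A monotone curve returns the grid boundary with a
#' warning and `boundary = TRUE`.
#'
#' @param model A `coupling_model`.
#' @param grid RATIO values to search; defaults to a fine grid over the fit
#'   domain.
#' @param direction `"max"` (default) or `"min"`.
#' @return A list with `ratio` (extremum location), `value`, and `boundary`.
#' @export
peak_location <- function(model, grid = NULL,
                          direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (is.null(grid)) {
    grid <- seq(model$fit_domain[1], model$fit_domain[2], length.out = 2001)
  }
  if (any(grid < model$fit_domain[1] - 1e-9 | grid > model$fit_domain[2] + 1e-9)) {
    abort("search grid extends beyond the model's fit domain.")
  }
  y <- predict(model, grid)
  idx <- if (direction == "max") which.max(y) else which.min(y)
  boundary <- idx == 1L || idx == length(grid)
  if (boundary) {
    warn(paste0("Extremum of ", model$variable,
                " curve lies on the search boundary (monotone curve?)."))
  }
  list(ratio = grid[idx], value = y[idx], boundary = boundary)
}

#' Per-bin discrepancy of one EC variable between two groups
#'
#' For two groups binned on identical edges, computes the absolute difference
#' of bin means in every bin populated by both, plus a separate summary over
#' bins with RATIO below 0.7, where the magnitudes of the same flux variable
#' across ecosystems are expected to be nearly equal.
#'
#' @param binned A `binned_series` holding (at least) the two groups.
#' @param group_a,group_b Group labels to contrast.
#' @return A list with `profile` (tibble: `bin_center`, `diff`, counts) and
#'   `mean_abs_diff_below_0p7`.
#' @export
between_group_discrepancy <- function(binned, group_a, group_b) {
  stopifnot(inherits(binned, "binned_series"))
  df <- as_tibble(binned)
  a <- filter(df, .data$group == group_a)
  b <- filter(df, .data$group == group_b)
  prof <- dplyr::inner_join(
    select(a, "bin", "bin_center", mean_a = "bin_mean", n_a = "bin_count"),
    select(b, "bin", mean_b = "bin_mean", n_b = "bin_count"),
    by = "bin"
  ) |>
    mutate(diff = abs(.data$mean_a - .data$mean_b))
  if (nrow(prof) == 0) {
    warn("The two groups populate disjoint bins; empty discrepancy profile.")
    return(list(profile = prof, mean_abs_diff_below_0p7 = NA_real_))
  }
  list(
    profile = prof,
    mean_abs_diff_below_0p7 = mean(prof$diff[prof$bin_center < 0.7])
  )
}
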