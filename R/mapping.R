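#' Map EC observations to another place through its daily RATIOs
#'
#' Implements the transfer principle that for a common daily RATIO the
#' magnitude of an EC variable is (approximately) the same in any two
#' ecosystems or places: each target site-day's value of a variable is
#' predicted by evaluating a coupling model fitted elsewhere at the target's
#' observed daily RATIO. Target days whose RATIO falls outside a model's fit
#' domain are excluded and counted.
#'
#' @param source_models Named list of `coupling_model`s (names are EC
#'   variables), fitted on the source group.
#' @param target_summaries Filtered site-day summaries of the target group;
#'   must hold the observed columns for the mapped variables.
#' @param variables Variables to map; defaults to the names of
#'   `source_models`.
#' @return A tibble with one row per (target site-day, variable): `site_id`,
#'   `date`, `ratio`, `variable`, `predicted`, `observed`, plus an
#'   `n_out_of_domain` attribute.
#' @export
map_observations <- function(source_models, target_summaries,
                             variables = names(source_models)) {
  missing_models <- setdiff(variables, names(source_models))
  if (length(missing_models) > 0) {
    abort(paste0("No source model for variable(s): ",
                 paste(missing_models, collapse = ", ")))
  }
  stop_if_missing_cols(target_summaries, c("site_id", "date", "ratio"),
                       "target summaries")
  n_ood_total <- 0L
  rows <- purrr::map(variables, function(v) {
    m <- source_models[[v]]
    obs_col <- if (v %in% names(target_summaries)) target_summaries[[v]] else {
      abort(paste0("Target summaries lack observed column '", v, "'."))
    }
    in_dom <- !is.na(target_summaries$ratio) &
      target_summaries$ratio >= m$fit_domain[1] &
      target_summaries$ratio <= m$fit_domain[2]
    n_ood <- sum(!is.na(target_summaries$ratio) & !in_dom)
    n_ood_total <<- n_ood_total + n_ood
    t <- target_summaries[in_dom, ]
    tibble(site_id = t$site_id, date = t$date, ratio = t$ratio,
           variable = v,
           predicted = predict(m, t$ratio),
           observed = obs_col[in_dom])
  })
  out <- bind_rows(rows)
  if (n_ood_total > 0) {
    inform(paste0(n_ood_total,
                  " target site-day/variable pairs fell outside the source fit domain and were excluded."))
  }
  attr(out, "n_out_of_domain") <- n_ood_total
  out
}

#' Evaluate mapped predictions against observations
#'
#' Per variable and per land-cover (or any) group, computes the Pearson
#' correlation between predicted and observed daily values, its two-sided
#' p value, the RMSE and the pair count. An `"all"` group pooling every pair
#' is always included. Groups with fewer than 3 pairs, or with zero variance
#' in either vector, are reported with `r = NA` and a `reason`.
#'
#' @param mapped Tibble from [map_observations()].
#' @param metadata Optional site metadata used to attach the grouping column.
#' @param group_by Name of the grouping column (default `"group"`, the
#'   land-cover class); `NULL` evaluates only the pooled group.
#' @return A `mapping_result` tibble: `variable`, `group`, `r`, `p_value`,
#'   `rmse`, `n`, `reason`.
#' @export
evaluate_mapping <- function(mapped, metadata = NULL, group_by = "group") {
  stop_if_missing_cols(mapped, c("variable", "predicted", "observed"), "mapped")
  df <- mapped
  if (!is.null(group_by) && !group_by %in% names(df)) {
    if (is.null(metadata)) {
      abort(paste0("Column '", group_by,
                   "' absent from `mapped`; supply `metadata` to join it."))
    }
    df <- left_join(df, select(metadata, "site_id", dplyr::all_of(group_by)),
                    by = "site_id")
  }
  eval_one <- function(d, label) {
    d <- filter(d, !is.na(.data$predicted), !is.na(.data$observed))
    n <- nrow(d)
    if (n < 3) {
      return(tibble(group = label, r = NA_real_, p_value = NA_real_,
                    rmse = NA_real_, n = n, reason = "fewer than 3 pairs"))
    }
    if (sd(d$predicted) == 0 || sd(d$observed) == 0) {
      return(tibble(group = label, r = NA_real_, p_value = NA_real_,
                    rmse = sqrt(mean((d$predicted - d$observed)^2)), n = n,
                    reason = "zero variance"))
    }
    ct <- cor.test(d$predicted, d$observed)
    tibble(group = label, r = unname(ct$estimate), p_value = ct$p.value,
           rmse = sqrt(mean((d$predicted - d$observed)^2)), n = n,
           reason = NA_character_)
  }
  out <- df |>
    group_by(.data$variable) |>
    dplyr::group_modify(function(d, key) {
      res <- eval_one(d, "all")
      if (!is.null(group_by)) {
        per <- d |>
          group_by(.data[[group_by]]) |>
          dplyr::group_map(~ eval_one(.x, as.character(.y[[1]]))) |>
          bind_rows()
        res <- bind_rows(res, per)
      }
      res
    }) |>
    ungroup()
  structure(out, class = c("mapping_result", class(out)))
}
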