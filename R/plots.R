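#' @export
autoplot.binned_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin_center, y = .data$bin_mean,
                               colour = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$bin_count), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "daily RATIO", y = attr(object, "variable"),
                  colour = NULL, size = "n") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coupling_model <- function(object, n = 400, ...) {
  grid <- seq(object$fit_domain[1], object$fit_domain[2], length.out = n)
  df <- tibble(ratio = grid, fitted = predict(object, grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$fitted)) +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = "daily RATIO", y = object$variable,
                  title = paste0(object$variable, " ~ daily RATIO (",
                                 object$family, ", R² = ",
                                 round(object$goodness, 3), ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trend_curve <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$bin_center)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$r_q05, ymax = .data$r_q95),
                         fill = "#92c5de", alpha = 0.5) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$r_q25, ymax = .data$r_q75),
                         fill = "#4393c3", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$r_median), colour = "#053061") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$critical_r,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "daily RATIO", y = "trend coefficient r",
                  title = paste0(object$variable,
                                 ": temporal trend vs daily RATIO")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lai_ratio_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lai_bin_center, y = .data$mean_ratio)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ratio - .data$sd_ratio,
                                      ymax = .data$mean_ratio + .data$sd_ratio),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(colour = "#1b7837") +
    ggplot2::labs(x = "LAI", y = "daily RATIO") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mapping_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$variable, y = .data$r,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "predicted-observed r", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
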