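#' Plot regional coral-cover trends
#'
#' Site-year cover as light points with the basin-wide annual mean and
#' standard-error ribbon overlaid, in the style of regional monitoring
#' summaries.
#'
#' @param series Site-year tibble from [annual_series()].
#' @return A ggplot object.
#' @export
plot_cover_trends <- function(series) {
  reg <- regional_means(series)
  ggplot2::ggplot(series, ggplot2::aes(x = .data$year, y = .data$total_cover)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "grey50") +
    ggplot2::geom_ribbon(
      data = reg,
      ggplot2::aes(y = .data$mean_cover,
                   ymin = .data$mean_cover - .data$se,
                   ymax = .data$mean_cover + .data$se),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(data = reg, ggplot2::aes(y = .data$mean_cover),
                       colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = "Year", y = "Total coral cover (%)",
                  title = "Regional coral cover trend") +
    ggplot2::theme_minimal()
}

#' Plot decadal summaries
#'
#' Point-range plot of per-decade group means with bootstrap confidence
#' limits (e.g. annual rate of cover change for impacted vs control reefs).
#'
#' @param summary Tibble from [decadal_summary()].
#' @param group Optional grouping column name to colour by (e.g.
#'   `"category"`).
#' @return A ggplot object.
#' @export
plot_decadal_summary <- function(summary, group = NULL) {
  aes <- if (!is.null(group)) {
    ggplot2::aes(x = factor(.data$decade), y = .data$mean,
                 ymin = .data$ci_lo, ymax = .data$ci_hi,
                 colour = .data[[group]])
  } else {
    ggplot2::aes(x = factor(.data$decade), y = .data$mean,
                 ymin = .data$ci_lo, ymax = .data$ci_hi)
  }
  ggplot2::ggplot(summary, aes) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "Decade", y = "Mean (bootstrap CI)") +
    ggplot2::theme_minimal()
}

#' Plot a segmented fit
#'
#' Data with the fitted segments and breakpoint locations.
#'
#' @param object A [piecewise_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.piecewise_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "tomato",
                       linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = object$breakpoints, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(title = "Segmented linear fit",
                  subtitle = paste("breakpoints:",
                                   paste(signif(object$breakpoints, 4),
                                         collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' Residual diagnostics plot for a resilience mixed model
#'
#' Residuals against fitted values plus a normal quantile-quantile panel,
#' the standard checks of homoscedasticity and residual normality.
#'
#' @param object A [fit_resilience_lmm()] object.
#' @param ... Unused.
#' @return A ggplot object (two panels via facetting).
#' @export
autoplot.reefstorm_lmm <- function(object, ...) {
  res <- lmm_residuals(object)
  qq <- stats::qqnorm(res$residual, plot.it = FALSE)
  plot_dat <- dplyr::bind_rows(
    tibble::tibble(panel = "residuals vs fitted", x = res$fitted, y = res$residual),
    tibble::tibble(panel = "normal Q-Q", x = qq$x, y = qq$y)
  )
  ggplot2::ggplot(plot_dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Mixed-model residual diagnostics") +
    ggplot2::theme_minimal()
}
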