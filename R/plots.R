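# ggplot2 views of the main result types.

#' Box-and-whisker view of exposure distributions
#'
#' Boxes at the 25th/50th/75th percentiles with whiskers at the 5th and
#' 95th, one panel per metric — the standard display for comparing
#' steady-state exposure distributions across populations.
#'
#' @param metrics Tibble from [steady_state_metrics()], optionally with a
#'   `population` column to compare groups.
#' @return A ggplot object.
#' @export
plot_exposure_distribution <- function(metrics) {
  long <- metrics |>
    tidyr::pivot_longer(dplyr::any_of(c("auc24", "cmax", "c24")),
                        names_to = "metric", values_to = "value")
  if (!"population" %in% names(long)) long$population <- "simulated"
  sum_tbl <- long |>
    dplyr::group_by(.data$metric, .data$population) |>
    dplyr::summarise(
      p5 = stats::quantile(.data$value, 0.05),
      p25 = stats::quantile(.data$value, 0.25),
      p50 = stats::quantile(.data$value, 0.50),
      p75 = stats::quantile(.data$value, 0.75),
      p95 = stats::quantile(.data$value, 0.95),
      .groups = "drop"
    )
  ggplot2::ggplot(sum_tbl, ggplot2::aes(x = .data$population)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$p5, lower = .data$p25, middle = .data$p50,
                   upper = .data$p75, ymax = .data$p95),
      stat = "identity", width = 0.5
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "steady-state exposure") +
    ggplot2::theme_bw()
}

#' Exposure-response plot: model band plus observed quartiles
#'
#' The fitted response curve with its 95% confidence band over the 5th-95th
#' exposure percentiles, overlaid with the observed responder proportion and
#' exact 95% CI in each exposure quartile (plotted at the quartile's median
#' exposure).
#'
#' @param object An `er_fit` from [fit_er_model()].
#' @param quartiles Optional [quartile_summary()] tibble to overlay.
#' @param band Optional precomputed [prediction_band()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.er_fit <- function(object, quartiles = NULL, band = NULL, ...) {
  if (is.null(band)) band <- prediction_band(object)
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$exposure)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$prediction)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = sprintf("steady-state %s", object$metric),
      y = "proportion responding"
    ) +
    ggplot2::theme_bw()
  if (!is.null(quartiles)) {
    q <- dplyr::filter(quartiles, .data$n > 0)
    p <- p +
      ggplot2::geom_pointrange(
        data = q,
        ggplot2::aes(x = .data$exposure_median, y = .data$proportion,
                     ymin = .data$conf.low, ymax = .data$conf.high)
      )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
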