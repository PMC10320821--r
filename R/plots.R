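#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a partial-effect curve with its bootstrap band
#'
#' Line plus ribbon for the output of [bootstrap_ci()] (or any tibble with
#' `x`, `estimate`, `lower`, `upper`).
#'
#' @param band Tibble from [bootstrap_ci()].
#' @param xlab,ylab Axis labels.
#' @return A ggplot.
#' @export
plot_effect_band <- function(band, xlab = "word property", ylab = "slowdown (ms)") {
  ggplot2::ggplot(band, ggplot2::aes(x = .data$x, y = .data$estimate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey70", alpha = 0.5
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a fitted reading-time model's univariate partial effects
#'
#' @param object A `reading_gam_fit`.
#' @param vars Covariates to plot (defaults to the fit's univariate smooths
#'   of surprisal / frequency / length).
#' @param n Grid points per curve.
#' @param ... Unused.
#' @return A ggplot, one facet per property.
#' @export
autoplot.reading_gam_fit <- function(object, vars = NULL, n = 100, ...) {
  if (is.null(vars)) {
    vars <- intersect(
      c("surp", "freq", "length"),
      unlist(lapply(object$fit$smooth, function(s) if (length(s$term) == 1) s$term))
    )
  }
  d <- purrr::map_dfr(vars, function(v) {
    g <- seq(object$ranges[[v]][1], object$ranges[[v]][2], length.out = n)
    tibble::tibble(property = v, x = g, effect = as.numeric(partial_effect(object, v, g)))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$effect)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::facet_wrap(~property, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "partial effect (ms)") +
    ggplot2::theme_minimal()
}

#' Plot group mean slowdown effects with confidence intervals
#'
#' Point-range plot of per-participant slowdown effects by group, property
#' and measure (the magnitude-comparison view).
#'
#' @param slowdowns Tibble from [compute_slowdowns()] joined with a `group`
#'   column (e.g. via participant profiles).
#' @return A ggplot.
#' @export
plot_slowdowns <- function(slowdowns) {
  stopifnot("group" %in% names(slowdowns))
  d <- slowdowns |>
    dplyr::group_by(.data$group, .data$measure, .data$property) |>
    dplyr::summarise(
      mean = mean(.data$slowdown, na.rm = TRUE),
      se = stats::sd(.data$slowdown, na.rm = TRUE) / sqrt(sum(!is.na(.data$slowdown))),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$property, y = .data$mean, colour = .data$group
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$mean - stats::qnorm(0.975) * .data$se,
        ymax = .data$mean + stats::qnorm(0.975) * .data$se
      ),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "mean slowdown (ms)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the proficiency curve against the L1 reference
#'
#' @param curve Output of [fit_proficiency_curve()].
#' @param records Optional records tibble to overlay the per-participant
#'   points.
#' @return A ggplot.
#' @export
plot_proficiency_curve <- function(curve, records = NULL) {
  p <- ggplot2::ggplot(curve$curve, ggplot2::aes(x = .data$mpt, y = .data$estimate))
  if (!is.null(records)) {
    p <- p + ggplot2::geom_point(
      data = records[records$english == 0, ],
      ggplot2::aes(x = .data$mpt, y = .data$response),
      colour = "#2166ac", alpha = 0.4, inherit.aes = FALSE
    )
  }
  p <- p +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "#2166ac", alpha = 0.2
    ) +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.8)
  if (is.finite(curve$l1$mean)) {
    p <- p +
      ggplot2::geom_hline(yintercept = curve$l1$mean, colour = "#b2182b") +
      ggplot2::geom_hline(
        yintercept = c(curve$l1$lower, curve$l1$upper),
        colour = "#b2182b", linetype = "dashed", alpha = 0.6
      )
  }
  p + ggplot2::labs(x = "proficiency score", y = "slowdown (ms)") +
    ggplot2::theme_minimal()
}
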