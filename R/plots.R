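#' Plot per-profile widths of one measurement
#'
#' Valid per-profile widths along the channel axis with the image mean
#' drawn as a dashed line; invalid profiles appear as rug marks at the
#' bottom.
#'
#' @param object a `width_measurement`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.width_measurement <- function(object, ...) {
  pr <- object$profiles
  ggplot2::ggplot(pr[pr$valid, ],
                  ggplot2::aes(x = .data$position_um, y = .data$width_um)) +
    ggplot2::geom_point(size = 0.8, colour = "#00688B") +
    ggplot2::geom_hline(yintercept = object$mean_width, linetype = 2) +
    ggplot2::geom_rug(data = pr[!pr$valid, ],
                      ggplot2::aes(x = .data$position_um), inherit.aes = FALSE,
                      sides = "b", colour = "firebrick") +
    ggplot2::labs(
      x = "position along channel (µm)",
      y = "projected width (µm)",
      title = sprintf("chip %s, day %s: mean %.1f µm (%d/%d profiles)",
                      object$chip_id, object$day, object$mean_width,
                      object$n_valid_profiles, object$n_profiles)) +
    ggplot2::theme_minimal()
}

#' Plot mixed-model predictions with confidence intervals
#'
#' Predicted per-day cell means by group with the fitted confidence
#' intervals as error bars; when the interval-overlap rule detects a
#' divergence day it is marked with a vertical line.
#'
#' @param object a `lumen_lmm` fit.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lumen_lmm <- function(object, ...) {
  preds <- object$predictions
  p <- ggplot2::ggplot(preds,
                       ggplot2::aes(x = .data$day, y = .data$estimate,
                                    colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.25, position = ggplot2::position_dodge(0.3)) +
    ggplot2::labs(x = "day", y = "projected width (µm)",
                  colour = NULL,
                  title = sprintf("LMM cell means with %.0f%% CIs",
                                  100 * object$ci_level)) +
    ggplot2::theme_minimal()
  if (length(object$groups) == 2) {
    div <- ci_divergence_day(object)
    if (!is.na(div$first_divergence_day)) {
      p <- p + ggplot2::geom_vline(xintercept = div$first_divergence_day,
                                   linetype = 3)
    }
  }
  p
}

#' Scatter plot of a longitudinal cohort
#'
#' One point per chip and day, coloured by group, with per-cell means
#' overlaid.
#'
#' @param cohort tibble with `chip_id`, `group`, `day`, `width_um`.
#' @return A ggplot.
#' @export
plot_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  means <- describe_widths(cohort)
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data$day, y = .data$width_um,
                               colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.45, size = 0.9) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(y = .data$mean_um), linewidth = 0.8) +
    ggplot2::labs(x = "day", y = "projected width (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram panel of shape descriptors by group
#'
#' @param shapes tibble from [shape_descriptors()].
#' @param descriptor descriptor column to show.
#' @param by faceting column (default `day` when present).
#' @return A ggplot.
#' @export
plot_morphology <- function(shapes, descriptor = "aspect_ratio",
                            by = "day") {
  stopifnot(descriptor %in% names(shapes))
  p <- ggplot2::ggplot(shapes,
                       ggplot2::aes(x = .data[[descriptor]])) +
    ggplot2::geom_histogram(bins = 30, fill = "#00688B", colour = "white") +
    ggplot2::labs(x = descriptor, y = "cells") +
    ggplot2::theme_minimal()
  if (by %in% names(shapes)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data[[by]]))
  }
  p
}
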