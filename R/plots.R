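#' Posterior density of the intervention effect
#'
#' Density of the condition fixed effect on the change scale with the HPDI
#' shaded; the dashed line marks the (signed) prior mean where an informative
#' prior was used, the solid line marks zero.
#'
#' @param object A `bayes_fit`.
#' @param level HPDI level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot bayes_fit
autoplot.bayes_fit <- function(object, level = 0.95, ...) {
  iv <- group_interval(object, level)
  dens <- stats::density(object$draws$beta_cwi)
  dd <- tibble::tibble(x = dens$x, y = dens$y)
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_area(data = dplyr::filter(dd, .data$x >= iv$lower,
                                            .data$x <= iv$upper),
                       fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Condition effect on pre-post change (s)",
                  y = "Posterior density",
                  title = paste0(object$outcome, ": ",
                                 round(level * 100), "% HPDI [",
                                 signif(iv$lower, 3), ", ",
                                 signif(iv$upper, 3), "]"))
  if (!identical(object$priors$slope_prior, "flat")) {
    sp <- object$priors$slope_prior
    pm <- if (sp$direction == "benefit_reduces_outcome") -sp$mean else sp$mean
    p <- p + ggplot2::geom_vline(xintercept = pm, linetype = "dashed")
  }
  p
}

#' Dot-and-whisker interval panels for a full analysis
#'
#' Group- and individual-level intervals for every outcome and approach in
#' one faceted display, subjects ordered as in the report (Bayesian posterior
#' mean for the first outcome).  Negative values mean benefit for time-like
#' outcomes; the solid vertical line marks zero.
#'
#' @param object An `analysis_report`.
#' @param which `"individual"` (default) or `"group"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot analysis_report
autoplot.analysis_report <- function(object, which = c("individual", "group"),
                                     ...) {
  which <- match.arg(which)
  if (which == "group") {
    df <- dplyr::mutate(object$group_results, unit = "group")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$approach)) +
      ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                           xmax = .data$upper),
                              height = 0.15) +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(~outcome, scales = "free_x") +
      ggplot2::labs(x = "Difference in pre-post change, intervention - control (s)",
                    y = NULL)
  } else {
    df <- object$individual_results |>
      dplyr::mutate(subject = factor(.data$subject,
                                     levels = rev(object$subject_order)))
    pts <- object$raw_differences |>
      dplyr::mutate(subject = factor(.data$subject,
                                     levels = rev(object$subject_order)))
    ggplot2::ggplot(df, ggplot2::aes(y = .data$subject,
                                     colour = .data$approach)) +
      ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                           xmax = .data$upper),
                              position = ggplot2::position_dodge(width = 0.6),
                              height = 0.3) +
      ggplot2::geom_point(ggplot2::aes(x = .data$estimate),
                          position = ggplot2::position_dodge(width = 0.6)) +
      ggplot2::geom_point(data = pts,
                          ggplot2::aes(x = .data$difference, y = .data$subject),
                          inherit.aes = FALSE, shape = 4) +
      ggplot2::facet_wrap(~outcome, scales = "free_x") +
      ggplot2::labs(x = "Difference in pre-post change, intervention - control (s)",
                    y = "Subject", colour = "Approach")
  }
}
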