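#' Volcano plot of differential methylation
#'
#' Delta mean versus `-log10(p)`, with the calling thresholds drawn as
#' dashed guides and calls colored.
#'
#' @param calls Output of [call_dmrs()].
#' @param delta_threshold,p_threshold The thresholds to draw (defaults
#'   match [call_dmrs()]).
#' @return A ggplot object.
#' @export
plot_volcano <- function(calls, delta_threshold = 0.2, p_threshold = 0.05) {
  ggplot2::ggplot(calls, ggplot2::aes(
    x = .data$delta_mean, y = .data$neg_log10_p, colour = .data$call
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(
      xintercept = c(-delta_threshold, delta_threshold), linetype = "dashed"
    ) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(hyper = "#d62728", hypo = "#1f77b4", ns = "grey70")
    ) +
    ggplot2::labs(
      x = "delta mean (tumor - normal, scaled ams)",
      y = expression(-log[10] ~ p), colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Quadrant plot of methylation versus expression change
#'
#' @param quadrants Output of [assign_quadrants()].
#' @param delta_threshold,fc_threshold_log2 Guides to draw.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(quadrants, delta_threshold = 0.2,
                           fc_threshold_log2 = log2(1.2)) {
  ggplot2::ggplot(quadrants, ggplot2::aes(
    x = .data$delta_mean, y = .data$log2_fold_change, colour = .data$quadrant
  )) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_vline(
      xintercept = c(-delta_threshold, delta_threshold), linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = c(-fc_threshold_log2, fc_threshold_log2), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "delta mean (methylation)", y = expression(log[2] ~ "fold change"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for grouped survival records
#'
#' Estimates one product-limit curve per group and draws them as step
#' functions with censoring marks.
#'
#' @param records Data frame with `time`, `event`, `group`.
#' @return A ggplot object.
#' @export
plot_km <- function(records) {
  records <- check_survival_records(records)
  curves <- records |>
    dplyr::group_split(.data$group) |>
    purrr::map_dfr(function(g) {
      fit <- km_estimate(g)
      dplyr::bind_rows(
        tibble::tibble(time = 0, survival = 1),
        fit$steps[, c("time", "survival")]
      ) |>
        dplyr::mutate(group = g$group[1L])
    })
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$time, y = .data$survival, colour = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.km_fit <- function(object, ...) {
  steps <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    object$steps[, c("time", "survival")]
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.melting_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$temperature, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)", y = "-dF/dT") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hrm_calibration <- function(object, ...) {
  ggplot2::ggplot(object$standards, ggplot2::aes(
    x = .data$metric, y = .data$known_percent
  )) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, colour = "grey50"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "AUC metric", y = "percent methylation") +
    ggplot2::theme_minimal()
}
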