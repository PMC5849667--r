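#' @method autoplot ba_agreement
#' @export
autoplot.ba_agreement <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_conc, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = object$clinical_limits,
                        linetype = "dotted", colour = "firebrick") +
    ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$mean_ratio) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Mean concentration (µg/L)",
      y = paste0("Ratio ", object$ratio_direction),
      title = "Bland-Altman ratio agreement",
      subtitle = sprintf("mean ratio %.2f, 95%% LoA %.2f–%.2f",
                         object$mean_ratio, object$loa[1], object$loa[2])
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot pb_fit
#' @export
autoplot.pb_fit <- function(object, ...) {
  rng <- range(object$data$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, rng[2]), ylim = c(0, NA)) +
    ggplot2::labs(
      x = "Comparator concentration (µg/L)",
      y = "Reference concentration (µg/L)",
      title = "Passing-Bablok regression",
      subtitle = sprintf("slope %.2f, intercept %.2f", object$slope,
                         object$intercept)
    ) +
    ggplot2::theme_minimal()
}

#' Per-patient prediction-error plot
#'
#' Percentage prediction error for each patient with guides at the
#' acceptance band (default +/- 20%).
#'
#' @param metrics A [prediction_metrics()] object.
#' @return A ggplot object.
#' @export
plot_prediction_errors <- function(metrics) {
  stopifnot(inherits(metrics, "prediction_metrics"))
  d <- metrics$errors
  ggplot2::ggplot(d, ggplot2::aes(x = .data$patient_id, y = .data$pct_error)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * metrics$within_pct,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Patient", y = "Percentage prediction error (%)",
      title = "Leave-one-out prediction errors"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
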