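#' Plot a Shannon-entropy conservation profile
#'
#' @param profile Tibble from [entropy_profile()]; a `region` column, if
#'   present, is used for facetting.
#' @return A ggplot object.
#' @export
plot_entropy <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = factor(.data$position), y = .data$entropy)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = log(4), linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "23S position", y = "Shannon entropy (nats)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
  if ("region" %in% names(profile)) {
    p <- p + ggplot2::facet_grid(~region, scales = "free_x", space = "free_x")
  }
  p
}

#' Plot per-position mutational flexibility scores
#'
#' Bar chart of flexibility scores with the score >= 1 threshold marked;
#' positions where at least one mutant reaches 75% of wild-type activity
#' are starred.
#'
#' @param scores Tibble from [flexibility_scores()].
#' @return A ggplot object.
#' @export
plot_flexibility <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = factor(.data$position), y = .data$score)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$flag_flex_ge_1)) +
    ggplot2::geom_hline(yintercept = 1, colour = "red", linetype = "dashed") +
    ggplot2::geom_text(data = dplyr::filter(scores, .data$flag_any_ge_75pct),
                       ggplot2::aes(label = "*"), vjust = -0.2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue"),
                               name = "score >= 1") +
    ggplot2::labs(x = "23S position", y = "Mutational flexibility score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Plot protein-synthesis kinetic traces
#'
#' @param traces Long tibble `sample_id`, `time_h`, `signal` (replicates
#'   averaged per time point for display).
#' @return A ggplot object.
#' @export
plot_kinetics <- function(traces) {
  avg <- traces |>
    dplyr::group_by(.data$sample_id, .data$time_h) |>
    dplyr::summarise(signal = mean(.data$signal), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$time_h, y = .data$signal,
                                    colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Signal", colour = "Sample") +
    ggplot2::theme_minimal()
}

#' Plot a sucrose-gradient trace with species windows
#'
#' @param trace Tibble `distance_mm`, `a254` (corrected or raw).
#' @param boundaries Species windows; default [default_boundaries()].
#' @return A ggplot object.
#' @export
plot_gradient <- function(trace, boundaries = default_boundaries()) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$distance_mm, y = .data$a254)) +
    ggplot2::geom_rect(data = boundaries, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -Inf, ymax = Inf, fill = .data$species),
                       alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Gradient distance (mm)", y = "A254", fill = "Species") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rfu, y = .data$um)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "Fluorescence (RFU)", y = "Concentration (uM)",
                  title = sprintf("Standard curve (R^2 = %.4f)", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @method autoplot flex_lm
#' @export
autoplot.flex_lm <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(title = sprintf("R^2 = %.3f, P = %.3g", object$r_squared, object$p_value)) +
    ggplot2::theme_minimal()
}
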