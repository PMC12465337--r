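#' Plot metric trajectories
#'
#' Baseline-normalized trajectories per well (thin lines) with per-condition
#' means (thick lines); detected death events are marked with black squares
#' at the death day, matching the timewise plots used for longitudinal
#' culture screens.
#'
#' @param object A `metric_trajectories` tibble.
#' @param metric Which metric to plot (default: first present).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot metric_trajectories
autoplot.metric_trajectories <- function(object, metric = NULL, ...) {
  metric <- metric %||% object$metric[1]
  d <- dplyr::filter(object, .data$metric == !!metric)
  cond_mean <- d |>
    dplyr::filter(.data$dead == 0) |>
    dplyr::group_by(.data$condition, .data$day) |>
    dplyr::summarise(normalized = mean(.data$normalized, na.rm = TRUE),
                     .groups = "drop")
  deaths <- dplyr::filter(d, !is.na(.data$death_day),
                          .data$day == .data$death_day)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$normalized,
                                       colour = .data$condition)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$well), alpha = 0.35) +
    ggplot2::geom_line(data = cond_mean, linewidth = 1.1) +
    ggplot2::labs(x = "imaging day", y = paste0(metric, " (normalized)"),
                  colour = "condition") +
    ggplot2::theme_minimal()
  if (nrow(deaths) > 0) {
    p <- p + ggplot2::geom_point(data = deaths, shape = 15, size = 2.5,
                                 colour = "black")
  }
  p
}

#' AUC boxplots per experimental factor
#'
#' @param auc_design AUC table joined to the design (columns `metric`,
#'   `auc`, `media`, `laminin`, `density`).
#' @return A ggplot object faceted by metric and factor.
#' @export
plot_auc_by_factor <- function(auc_design) {
  long <- tidyr::pivot_longer(auc_design,
                              cols = c("media", "laminin", "density"),
                              names_to = "factor", values_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.colour = "red", outlier.shape = 4) +
    ggplot2::facet_grid(metric ~ factor, scales = "free") +
    ggplot2::labs(x = NULL, y = "trajectory AUC") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a factorial fit
#'
#' @param object A `factorial_fit`.
#' @param ... Unused.
#' @return A ggplot object of effect estimates with ±2 SE bars.
#' @exportS3Method ggplot2::autoplot factorial_fit
autoplot.factorial_fit <- function(object, ...) {
  d <- dplyr::filter(object$terms, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term,
                                                     .data$estimate))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 2 * .data$std.error,
      xmax = .data$estimate + 2 * .data$std.error), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "effect on AUC", y = NULL) +
    ggplot2::theme_minimal()
}
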