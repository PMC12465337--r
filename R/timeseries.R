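#' Normalize a metric series to its first-day value
#'
#' Each value is divided by the value at the first imaging day, so every
#' well starts at 1 and trajectories are comparable across wells.
#'
#' @param values Numeric vector ordered by day.
#' @return Normalized vector; all-`NA` with a warning if the baseline is 0.
#' @export
normalize_to_baseline <- function(values) {
  if (length(values) == 0) return(values)
  if (is.na(values[1]) || values[1] == 0) {
    warning("zero or missing baseline: series marked missing")
    return(rep(NA_real_, length(values)))
  }
  values / values[1]
}

#' Detect a death event in a fluorescence series
#'
#' A culture is considered non-viable from the first timepoint at which its
#' mean fluorescence intensity decreased by more than `threshold`
#' (strictly; default 10%) relative to the previous measurement. Steps with
#' a zero previous value are skipped (logged).
#'
#' @param values Mean fluorescence per day, ordered by day (>= 2 points).
#' @param days Optional day labels (defaults to `seq_along(values)`);
#'   the returned death day is taken from this vector.
#' @param threshold Fractional drop that defines death (default 0.10).
#' @return The death day, or `NA` if no death event occurs.
#' @export
detect_death_event <- function(values, days = seq_along(values),
                               threshold = 0.10) {
  if (length(values) < 2) {
    abort_param("values", "needs at least 2 timepoints")
  }
  stopifnot(length(days) == length(values))
  for (d in 2:length(values)) {
    prev <- values[d - 1]
    if (is.na(prev) || is.na(values[d])) next
    if (prev == 0) {
      message("zero intensity at day ", days[d - 1],
              ": death comparison skipped")
      next
    }
    if ((values[d] - prev) / prev < -threshold) return(days[d])
  }
  NA_integer_ * 1L
}

#' Trapezoidal AUC of a metric trajectory
#'
#' Area under the (normalized) trajectory by the trapezoid rule with true
#' day spacing, truncated at the death event: by default the death day
#' itself is excluded (the culture is non-viable at that timepoint);
#' `include_death_day = TRUE` keeps it.
#'
#' @param values Numeric metric values ordered by day.
#' @param days Numeric day labels (same length, strictly increasing).
#' @param death_day Optional death day; timepoints at/after it are dropped.
#' @param include_death_day Keep the death-day observation itself.
#' @return AUC in metric x days, or `NA` when fewer than 2 surviving
#'   timepoints remain.
#' @export
trajectory_auc <- function(values, days = seq_along(values),
                           death_day = NULL, include_death_day = FALSE) {
  stopifnot(length(days) == length(values))
  if (!is.null(death_day) && !is.na(death_day)) {
    keep <- if (include_death_day) days <= death_day else days < death_day
    values <- values[keep]; days <- days[keep]
  }
  ok <- !is.na(values)
  values <- values[ok]; days <- days[ok]
  if (length(values) < 2) return(NA_real_)
  sum(diff(days) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Assemble per-well metric trajectories
#'
#' Takes tidy per-image metric measurements, averages FOVs within each
#' (well, metric, day), normalizes each well's series to its first imaging
#' day, detects death events on the mean-fluorescence series of each well,
#' and flags post-death observations.
#'
#' @param metrics Tidy tibble with columns `well`, `condition`, `metric`,
#'   `day`, `value` (and optionally `fov`, averaged over).
#' @param intensity_metric Name of the metric used for death detection
#'   (default `"mean_fluorescence"`).
#' @param death_threshold Fractional drop defining death (default 0.10).
#' @return A `metric_trajectories` tibble: `well`, `condition`, `metric`,
#'   `day`, `raw`, `normalized`, `death_day`, `dead` (0/1 flag for
#'   observations at/after the death day).
#' @export
build_trajectories <- function(metrics, intensity_metric = "mean_fluorescence",
                               death_threshold = 0.10) {
  needed <- c("well", "condition", "metric", "day", "value")
  missing_cols <- setdiff(needed, names(metrics))
  if (length(missing_cols) > 0) {
    abort_param("metrics", paste("missing columns:",
                                 paste(missing_cols, collapse = ", ")))
  }
  daily <- metrics |>
    dplyr::group_by(.data$well, .data$condition, .data$metric, .data$day) |>
    dplyr::summarise(raw = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(.data$well, .data$metric, .data$day)

  deaths <- daily |>
    dplyr::filter(.data$metric == intensity_metric) |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(
      death_day = detect_death_event(.data$raw, .data$day,
                                     threshold = death_threshold),
      .groups = "drop")

  out <- daily |>
    dplyr::group_by(.data$well, .data$condition, .data$metric) |>
    dplyr::mutate(normalized = normalize_to_baseline(.data$raw)) |>
    dplyr::ungroup() |>
    dplyr::left_join(deaths, by = "well") |>
    dplyr::mutate(dead = as.integer(!is.na(.data$death_day) &
                                      .data$day >= .data$death_day))
  class(out) <- c("metric_trajectories", class(out))
  out
}

#' Summarise trajectories into per-well AUCs
#'
#' @param trajectories A `metric_trajectories` tibble from
#'   [build_trajectories()].
#' @param use_normalized Compute AUC on the baseline-normalized series
#'   (default) or on the raw series.
#' @param include_death_day Passed to [trajectory_auc()].
#' @return A tibble with `well`, `condition`, `metric`, `auc`, `death_day`.
#' @export
summarise_auc <- function(trajectories, use_normalized = TRUE,
                          include_death_day = FALSE) {
  col <- if (use_normalized) "normalized" else "raw"
  trajectories |>
    dplyr::group_by(.data$well, .data$condition, .data$metric) |>
    dplyr::summarise(
      auc = trajectory_auc(.data[[col]], .data$day,
                           death_day = .data$death_day[1],
                           include_death_day = include_death_day),
      death_day = .data$death_day[1],
      .groups = "drop")
}
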