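#' Plotting helpers
#'
#' ggplot2 views of the three result types: trial traces (timeline plus
#' lateral position), condition summaries (cell means with standard
#' errors), and training logs (smoothed episode returns).
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot ggplot aes geom_rect geom_line geom_hline
#'   geom_col geom_errorbar geom_point facet_wrap labs theme_minimal
#'   position_dodge
NULL

#' @export
ggplot2::autoplot

#' Timeline view of a trial
#'
#' Shades the timeline by attention (road / in-car / switching) and
#' overlays the car's lateral offset with the lane bounds.
#'
#' @param object A `trial_trace`.
#' @param lane_half_bound_m Lane bound drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_trace <- function(object, lane_half_bound_m = 1.75, ...) {
  ev <- object$events
  ev$phase <- ifelse(ev$kind == "switch", "switching",
                     ifelse(ev$kind == "drive_cycle", "road", "in-car"))
  ggplot(object$offsets, aes(x = .data$t, y = .data$offset_m)) +
    geom_rect(data = ev,
              aes(xmin = .data$t_start, xmax = .data$t_end,
                  ymin = -Inf, ymax = Inf, fill = .data$phase),
              alpha = 0.25, inherit.aes = FALSE) +
    geom_hline(yintercept = c(-1, 1) * lane_half_bound_m, linetype = 2) +
    geom_line() +
    labs(x = "time (s)", y = "lateral offset (m)", fill = "attention") +
    theme_minimal()
}

#' Condition-summary bar chart
#'
#' Cell means with standard-error bars, one facet per behaviour metric,
#' mirroring the usual presentation of dual-task driving results.
#'
#' @param object A `multitask_summary` from [aggregate_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multitask_summary <- function(object, ...) {
  df <- object
  df$condition <- sprintf("%g km/h\n%d items", df$speed_kmh, df$n_items)
  has_type <- "trial_type" %in% names(df)
  p <- ggplot(df, aes(x = .data$condition, y = .data$mean,
                      fill = if (has_type) .data$trial_type else NULL)) +
    geom_col(position = position_dodge(0.9)) +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se),
                  position = position_dodge(0.9), width = 0.3) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = "mean (SE)", fill = "trial type") +
    theme_minimal()
  p
}

#' Training-progress curve
#'
#' Episode returns with a running mean, for diagnosing whether a learner
#' converged.
#'
#' @param log Training log tibble (`episode`, `return`).
#' @param window Running-mean window in episodes.
#' @return A ggplot object.
#' @export
plot_training <- function(log, window = 50) {
  log$smooth <- stats::filter(log$return, rep(1 / window, window), sides = 1)
  ggplot(log, aes(x = .data$episode, y = .data$return)) +
    geom_point(alpha = 0.15, size = 0.4) +
    geom_line(aes(y = .data$smooth), colour = "firebrick", na.rm = TRUE) +
    labs(x = "episode", y = "return") +
    theme_minimal()
}
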