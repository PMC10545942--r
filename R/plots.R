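#' Plot tracked trajectories
#'
#' Draws every track's path in arena coordinates (y axis flipped to match
#' image convention). When a stimulus timeline or per-frame states are
#' supplied, path segments are coloured by stimulus state, the standard way
#' to show light-coupled behaviour on the tracks.
#'
#' @param track_table Track table from [track_animals()] / [run_pipeline()].
#' @param timeline Optional stimulus timeline (`time_s`, `value`) or state
#'   log; used to colour segments by state.
#' @return A ggplot object.
#' @export
plot_tracks <- function(track_table, timeline = NULL) {
  df <- track_table
  if (!is.null(timeline)) {
    tcol <- if ("time_s" %in% names(timeline)) "time_s" else "host_time_s"
    k <- findInterval(df$time_s, sort(timeline[[tcol]]))
    v <- timeline$value[order(timeline[[tcol]])]
    df$stimulus <- ifelse(k > 0 & v[pmax(k, 1)] > 0, "on", "off")
  } else {
    df$stimulus <- "off"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$track_id)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$stimulus), linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "stimulus") +
    ggplot2::theme_minimal()
  if (!is.null(timeline)) {
    p <- p + ggplot2::scale_colour_manual(values = c(off = "grey40", on = "red3"))
  } else {
    p <- p + ggplot2::scale_colour_manual(values = c(off = "grey30"), guide = "none")
  }
  p
}

#' Paired off-vs-on epoch statistics plot
#'
#' One point per track and state with lines joining the paired off/on values
#' — the standard presentation for paired stimulus comparisons.
#'
#' @param stats_tbl Output of [epoch_stats()].
#' @param metric `"displacement"` or `"mean_velocity"`.
#' @return A ggplot object.
#' @export
plot_epoch_stats <- function(stats_tbl, metric = c("displacement", "mean_velocity")) {
  metric <- match.arg(metric)
  df <- stats_tbl |>
    dplyr::group_by(.data$track_id, .data$state) |>
    dplyr::summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$track_id), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 2) +
    ggplot2::scale_colour_manual(values = c(off = "grey30", on = "red3"),
                                 guide = "none") +
    ggplot2::labs(x = "stimulus", y = metric) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.stimulus_timeline <- function(object, ...) {
  df <- as_tibble(object)
  end <- max(df$time_s) + if (nrow(df) > 1) mean(diff(df$time_s)) else 1
  df2 <- tibble(time_s = c(df$time_s, end), value = c(df$value, df$value[nrow(df)]))
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_step(colour = "red3") +
    ggplot2::labs(x = "time (s)", y = "light value (byte)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.quadratic_fit <- function(object, x = NULL, y = NULL, ...) {
  if (is.null(x)) x <- seq(0, 100, length.out = 200)
  pred <- tibble(x = x, y = apply_calibration(object, x))
  p <- ggplot2::ggplot(pred, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(colour = "blue3") +
    ggplot2::labs(x = "illuminance (sensor reading)",
                  y = "irradiance (uW/mm^2)",
                  subtitle = sprintf("R^2 = %.4f", object$r_squared)) +
    ggplot2::theme_minimal()
  if (!is.null(y)) {
    p <- p + ggplot2::geom_point(data = tibble(x = x, y = y), colour = "grey30")
  }
  p
}
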