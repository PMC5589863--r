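# ggplot2 views of the main result types.

#' Plot formation kinetics
#'
#' Spaghetti of normalised-area traces with the population median and
#' quartile envelope.
#'
#' @param object a [fit_formation()] result.
#' @param max_traces thin the spaghetti to at most this many traces.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.formation_fit <- function(object, max_traces = 50, ...) {
  d <- object$data
  ids <- unique(d$trace_id)
  if (length(ids) > max_traces) {
    d <- d |> filter(.data$trace_id %in% ids[seq_len(max_traces)])
  }
  col <- if ("area_norm" %in% names(d)) "area_norm" else object$area_col
  env <- object$data |>
    group_by(.data$t_h) |>
    summarise(
      med = median(.data[[col]]),
      q1 = quantile(.data[[col]], 0.25),
      q3 = quantile(.data[[col]], 0.75),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_h)) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[col]], group = .data$trace_id),
                       alpha = 0.2, colour = "steelblue") +
    ggplot2::geom_line(data = env, ggplot2::aes(y = .data$med), linewidth = 1) +
    ggplot2::geom_line(data = env, ggplot2::aes(y = .data$q1), linetype = 3) +
    ggplot2::geom_line(data = env, ggplot2::aes(y = .data$q3), linetype = 3) +
    ggplot2::labs(x = "time (h)", y = "normalized area",
                  title = sprintf("median tau = %.1f h",
                                  glance(object)$tau_median)) +
    ggplot2::theme_minimal()
}

#' Map of detected anchors
#'
#' @param anchors tibble from [detect_anchors()] (optionally with `region`).
#' @return a ggplot in physical units (um), y increasing downwards as in
#'   the images.
#' @export
plot_anchor_map <- function(anchors) {
  aes_pt <- if ("region" %in% names(anchors)) {
    ggplot2::aes(x = .data$col_um, y = .data$row_um, colour = .data$region)
  } else {
    ggplot2::aes(x = .data$col_um, y = .data$row_um)
  }
  ggplot2::ggplot(anchors, aes_pt) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot mean dead cells per spheroid over time
#'
#' @param series a [death_series()] result.
#' @return a ggplot, one line per region.
#' @export
plot_death_series <- function(series) {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$t_h, y = .data$n_dead_mean,
                               colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(I = "firebrick", II = "steelblue",
                                            III = "grey40")) +
    ggplot2::labs(x = "time (h)", y = "mean dead cells per spheroid") +
    ggplot2::theme_minimal()
}

#' Radial profile of a per-cell quantity
#'
#' Binned mean (with standard-error ribbon) of `value` against r/R.
#'
#' @param peaks tibble with `r_over_R` and the value column.
#' @param value column to profile (bare name or string).
#' @param bins number of radial bins.
#' @return a ggplot.
#' @export
plot_radial_profile <- function(peaks, value = "normalized", bins = 12) {
  value <- rlang::as_name(rlang::ensym(value))
  d <- peaks |>
    filter(is.finite(.data[[value]])) |>
    mutate(bin = cut(.data$r_over_R, breaks = seq(0, 1.2, length.out = bins + 1),
                     include.lowest = TRUE)) |>
    group_by(.data$bin) |>
    summarise(
      rr = mean(.data$r_over_R),
      m = mean(.data[[value]]),
      se = sd(.data[[value]]) / sqrt(n()),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rr, y = .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$se,
                                      ymax = .data$m + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r/R", y = value) +
    ggplot2::theme_minimal()
}

#' Tukey box plot with width proportional to sqrt(n)
#'
#' The study's box conventions: box q1-q3 with median line, mean as a black
#' dot, whiskers to the most extreme point within 1.5 IQR, box width
#' proportional to sqrt(n).
#'
#' @param data data frame.
#' @param value,group columns (bare names or strings).
#' @return a ggplot.
#' @export
plot_tukey_box <- function(data, value, group) {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  s <- tukey_box_list(split(data[[value]], data[[group]]))
  s$w <- 0.8 * s$box_width / max(s$box_width)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$whisker_low,
                                        ymax = .data$whisker_high),
                           width = 0.25) +
    ggplot2::geom_tile(ggplot2::aes(y = (.data$q1 + .data$q3) / 2,
                                    height = .data$q3 - .data$q1,
                                    width = .data$w),
                       fill = "grey85", colour = "black") +
    ggplot2::geom_segment(ggplot2::aes(
      x = as.numeric(factor(.data$group)) - .data$w / 2,
      xend = as.numeric(factor(.data$group)) + .data$w / 2,
      y = .data$median, yend = .data$median
    )) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), size = 2) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}
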