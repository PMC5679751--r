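#' Compass-style rose plot of movement directions
#'
#' Polar bar chart of the displacement-weighted direction proportions, with
#' the cardinal anatomical directions (A = animal, D = dorsal, Vg =
#' vegetal, V = ventral) marked on the compass.
#'
#' @param object A [rose_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rose_histogram <- function(object, ...) {
  conv <- attr(object, "convention") %||% direction_convention()
  df <- tibble::as_tibble(object)
  df$center <- (df$bin_start + (df$bin_end - df$bin_start) / 2) %% 360
  labs <- tibble::tibble(
    angle = unname(conv$labels),
    label = c("D", "A", "V", "Vg")[match(names(conv$labels),
                                         c("dorsal", "animal",
                                           "ventral", "vegetal"))]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$proportion)) +
    ggplot2::geom_col(width = 360 / nrow(df), fill = "steelblue",
                      colour = "grey30", alpha = 0.8) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-360 / nrow(df) / 2,
                                           360 - 360 / nrow(df) / 2),
                                breaks = labs$angle, labels = labs$label) +
    ggplot2::labs(x = NULL, y = "proportion of displacement") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of cell positions along the animal-vegetal axis
#'
#' @param object A [position_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.position_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$bin_start + df$bin_end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$frequency)) +
    ggplot2::geom_col(width = df$bin_end - df$bin_start,
                      fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "percent embryo height (VP = 0, AP = 100)",
                  y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot per-window group means of straightness and speed
#'
#' Mean with SEM error bars per genotype and time window, faceted by
#' metric.
#'
#' @param summary A tibble from [summarize_by_genotype()].
#' @return A ggplot object.
#' @export
plot_window_summary <- function(summary) {
  require_columns(summary, c("genotype", "window", "metric", "mean", "sem"),
                  "summary table")
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$window), y = .data$mean,
                               colour = .data$genotype,
                               group = .data$genotype)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.2, position = ggplot2::position_dodge(width = 0.3)
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time window", y = NULL) +
    ggplot2::theme_minimal()
}
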