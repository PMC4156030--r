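#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the hourglass-score trajectory of a simulation
#'
#' Shows the population median H (and robust H) across checkpoints with
#' an interquartile ribbon.
#'
#' @param object A `dgen_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dgen_sim <- function(object, ...) {
  tr <- object$trajectory |>
    dplyr::group_by(generation = .data$generation) |>
    dplyr::summarise(median_H = stats::median(.data$H),
                     q25 = stats::quantile(.data$H, 0.25),
                     q75 = stats::quantile(.data$H, 0.75), .groups = "drop")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_H), colour = "red") +
    ggplot2::labs(x = "generation", y = "hourglass score H",
                  title = sprintf("Model %d, N = %d", object$config$model,
                                  object$config$N)) +
    ggplot2::theme_minimal()
}

#' Plot the population width profile at the final generation
#'
#' Median stage width with interquartile range; an hourglass-shaped
#' population shows a clear minimum at the waist.
#'
#' @param sim A `dgen_sim`.
#' @return A ggplot object.
#' @export
plot_width_profile <- function(sim) {
  stopifnot(inherits(sim, "dgen_sim"))
  prof <- tidy(sim, long = TRUE) |>
    dplyr::filter(.data$generation == max(.data$generation)) |>
    dplyr::group_by(stage = .data$stage) |>
    dplyr::summarise(median = stats::median(.data$width),
                     q25 = stats::quantile(.data$width, 0.25),
                     q75 = stats::quantile(.data$width, 0.75),
                     .groups = "drop")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$stage, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey80") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq_len(sim$config$L)) +
    ggplot2::labs(x = "developmental stage", y = "stage width w(l)") +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#'
#' Hourglass score (normal and robust) and waist location as functions of
#' the transition threshold `c`.
#'
#' @param object A `threshold_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("H", "H_robust"), names_to = "score",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$c, y = .data$value,
                                     colour = .data$score)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "transition threshold c", y = "hourglass score") +
    ggplot2::theme_minimal()
}
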