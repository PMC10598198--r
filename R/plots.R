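#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an indifference curve
#'
#' The piecewise-linear equivalent small reward as a function of cost
#' level, with bin edges marked.
#'
#' @param object An `indifference_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.indifference_model <- function(object, ...) {
  C <- seq(0.005, 1, by = 0.005)
  df <- tibble::tibble(cost_level = C,
                       r_star = indifference_reward(C, object))
  ggplot2::ggplot(df, ggplot2::aes(.data$cost_level, .data$r_star)) +
    ggplot2::geom_vline(xintercept = seq(0.2, 0.8, 0.2),
                        linetype = "dotted", colour = "grey70") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "cost level (fraction of maximum)",
                  y = "equivalent small reward r*(C)") +
    ggplot2::theme_minimal()
}

#' Plot an indifference map
#'
#' Heat map of the indifference score over the reward-by-cost grid,
#' with the cost sampling density shown along the bottom.
#'
#' @param object An `indifference_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.indifference_map <- function(object, ...) {
  g <- object$grid
  df <- tidyr::expand_grid(small_reward = g$reward_levels,
                           cost_level = g$cost_levels)
  df$score <- as.vector(object$scores)  # rewards vary fastest (rows)
  ggplot2::ggplot(df, ggplot2::aes(.data$cost_level, .data$small_reward,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "indifference") +
    ggplot2::labs(x = "cost level", y = "small reward (fraction of 30€)") +
    ggplot2::theme_minimal()
}

#' Plot a model-selection result
#'
#' Expected frequencies and exceedance probabilities per model.
#'
#' @param object A `bms_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bms_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary, -"model",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sampler-comparison summary
#'
#' Balanced accuracy and mean posterior variance per sampler and trial
#' budget.
#'
#' @param object A `sampling_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sampling_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$summary,
    c("balanced_accuracy", "mean_posterior_variance"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$n_trials, .data$value,
                                   colour = .data$sampler)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "trials per cost type", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated session's mood trace and choices
#'
#' Mood rating (z-scored) across trials, coloured by episode condition,
#' with costly choices marked along the bottom.
#'
#' @param trials A trial-record tibble from [simulate_session()].
#' @return A ggplot.
#' @export
plot_mood_trace <- function(trials) {
  ggplot2::ggplot(trials, ggplot2::aes(.data$index, .data$mood_z)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition), size = 1) +
    ggplot2::geom_rug(data = trials[trials$choice == "costly", ],
                      sides = "b", alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(positive = "#E6B800",
                                            negative = "#3366CC",
                                            transition = "grey60")) +
    ggplot2::labs(x = "trial", y = "mood (z)") +
    ggplot2::theme_minimal()
}
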