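#' Plot the course of a training run
#'
#' Reward, van Rossum distance and maximum cross-correlation per episode,
#' one panel each, with a running-mean overlay.
#'
#' @param object An `xor_training` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xor_training <- function(object, ...) {
  long <- object$episodes |>
    dplyr::select(dplyr::all_of(c("episode", "reward", "distance", "crosscorr"))) |>
    tidyr::pivot_longer(-"episode", names_to = "metric") |>
    dplyr::mutate(metric = factor(
      .data$metric, levels = c("reward", "distance", "crosscorr"),
      labels = c("reward", "distance D(F,G)", "max cross-correlation")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$episode, y = .data$value)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, span = 0.3) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "episode", y = NULL,
                  title = "Temporally coded XOR training") +
    ggplot2::theme_minimal()
}

#' @export
plot.xor_training <- function(x, ...) print(autoplot.xor_training(x, ...))

#' Trajectories of the trained synaptic parameters
#'
#' One panel per parameter (`U_SE`, `tau_rec`, `tau_fac`); excitatory and
#' inhibitory eligible synapses are distinguished by colour.
#'
#' @param result An `xor_training` object.
#' @return A ggplot.
#' @export
plot_parameter_trajectories <- function(result) {
  df <- result$parameters |>
    dplyr::mutate(type = ifelse(.data$inhibitory, "inhibitory", "excitatory"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$episode, y = .data$value,
    group = .data$syn_id, colour = .data$type
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~parameter, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "episode", y = "parameter value", colour = NULL,
                  title = "Trained synaptic parameters") +
    ggplot2::theme_minimal()
}

#' Course of the time-averaged dynamic synaptic strength
#'
#' Per-episode `<S(t)> = <r u>` averaged within synapse groups
#' (trained/untrained x excitatory/inhibitory). Optionally min-max
#' normalized to \[0, 1\] per group, matching the usual presentation of
#' regime shifts at convergence.
#'
#' @param result An `xor_training` object.
#' @param normalize Min-max normalize each group's series; default TRUE.
#' @return A ggplot.
#' @export
plot_synaptic_strength <- function(result, normalize = TRUE) {
  df <- result$strength |>
    dplyr::mutate(group = paste(
      ifelse(.data$trained, "trained", "untrained"),
      ifelse(.data$inhibitory, "inhibitory", "excitatory")
    )) |>
    dplyr::group_by(.data$group, .data$episode) |>
    dplyr::summarise(mean_S = mean(.data$mean_S), .groups = "drop_last")
  if (normalize) {
    df <- df |>
      dplyr::mutate(mean_S = (.data$mean_S - min(.data$mean_S)) /
                      max(1e-12, diff(range(.data$mean_S))))
  }
  df <- dplyr::ungroup(df)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$episode, y = .data$mean_S, colour = .data$group
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(
      x = "episode",
      y = if (normalize) "<S> (min-max normalized)" else "<S>",
      colour = NULL, title = "Dynamic synaptic strength"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
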