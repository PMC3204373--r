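#' Tidy a training run
#'
#' @param x An `xor_training` object.
#' @param what Which table to return: per-episode `"episodes"` (default),
#'   the eligible-synapse `"parameters"` trajectories, or the per-synapse
#'   `"strength"` averages.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.xor_training <- function(x, what = c("episodes", "parameters", "strength"),
                              ...) {
  what <- match.arg(what)
  x[[what]]
}

#' One-row summary of a training run
#'
#' Last-50-episode means and SDs of the performance measures, alongside
#' the run geometry.
#'
#' @param x An `xor_training` object.
#' @param last_k Trailing window, default 50.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.xor_training <- function(x, last_k = 50, ...) {
  tail_ep <- dplyr::slice_tail(x$episodes, n = min(last_k, nrow(x$episodes)))
  tibble::tibble(
    n_episodes = nrow(x$episodes),
    n_hidden = x$config$n_hidden,
    window_ms = x$config$window_ms,
    seed = x$config$seed,
    mean_distance = mean(tail_ep$distance),
    sd_distance = stats::sd(tail_ep$distance),
    mean_crosscorr = mean(tail_ep$crosscorr),
    sd_crosscorr = stats::sd(tail_ep$crosscorr),
    mean_hit_raw = mean(tail_ep$hit_rate_raw),
    mean_hit_binned = mean(tail_ep$hit_rate_binned)
  )
}

#' @export
tidy.tm_network <- function(x, ...) {
  x$synapses
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
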