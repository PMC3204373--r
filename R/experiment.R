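#' Experiment configuration for the temporally coded XOR task
#'
#' Bundles everything a training run needs: network size, episode
#' geometry, stimulus statistics, metric settings, neuron and synapse
#' parameters, learning hyperparameters, and seeds. Defaults reproduce the
#' canonical protocol: 50-Hz Poisson inputs, 200-ms episodes on a 1-ms
#' grid, 5-ms binning window (40 bins), 300 episodes, distance filter
#' constant 15 ms.
#'
#' For window sweeps the episode length is chosen so the binned sequences
#' stay 40 steps long: `W = 4 -> L = 160`, `W = 5 -> L = 200`,
#' `W = 7 -> L = 280`.
#'
#' Randomness is split into named substreams derived from the master
#' `seed`: `seed_inputs` drives stimulus generation and `seed_topology`
#' the inhibitory-synapse assignment, so the topology can be held fixed
#' while inputs vary (or vice versa) by overriding one of them.
#'
#' @param n_hidden Hidden-layer size; default 7.
#' @param episode_ms Episode length L (ms); default 200.
#' @param dt Time step (ms); the canonical grid is 1 ms.
#' @param window_ms Binning window W (ms); default 5. Must divide
#'   `episode_ms`.
#' @param input_rate_hz Poisson input rate; default 50.
#' @param n_episodes Number of training episodes; default 300.
#' @param seed Master seed (integer).
#' @param seed_inputs,seed_topology Optional substream overrides.
#' @param tau_c van Rossum filter time constant (ms); default 15.
#' @param sigma_bins Gaussian filter width for the cross-correlation
#'   measure, in bins; default 1.
#' @param U_SE_init,tau_rec_init,tau_fac_init Initial synaptic parameters
#'   (defaults 0.5, 100 ms, 50 ms).
#' @param A Synaptic weight magnitude; default [default_A()].
#' @param literal_params Use the literal weight `A = 7e-4` (see
#'   [build_network()]).
#' @param neuron A `liaf_params` object.
#' @param learning A `learning_config` object.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_hidden = 7,
                              episode_ms = 200, dt = 1, window_ms = 5,
                              input_rate_hz = 50, n_episodes = 300,
                              seed = 1L,
                              seed_inputs = NULL, seed_topology = NULL,
                              tau_c = 15, sigma_bins = 1,
                              U_SE_init = 0.5, tau_rec_init = 100,
                              tau_fac_init = 50,
                              A = default_A(), literal_params = FALSE,
                              neuron = liaf_params(),
                              learning = learning_config()) {
  if (episode_ms %% window_ms != 0) {
    stop(sprintf("episode length %s ms is not divisible by window %s ms",
                 episode_ms, window_ms), call. = FALSE)
  }
  if (n_episodes < 2) stop("`n_episodes` must be at least 2", call. = FALSE)
  if (input_rate_hz * dt / 1000 >= 1) {
    stop("`input_rate_hz * dt` must stay below one spike per step",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  structure(
    list(
      n_hidden = as.integer(n_hidden),
      episode_ms = as.integer(episode_ms), dt = dt,
      window_ms = as.integer(window_ms),
      input_rate_hz = input_rate_hz,
      n_episodes = as.integer(n_episodes),
      seed = seed,
      seed_inputs = as.integer(seed_inputs %||% seed),
      seed_topology = as.integer(seed_topology %||% ((seed + 500009L) %% .Machine$integer.max)),
      tau_c = tau_c, sigma_bins = sigma_bins,
      U_SE_init = U_SE_init, tau_rec_init = tau_rec_init,
      tau_fac_init = tau_fac_init,
      A = A, literal_params = isTRUE(literal_params),
      neuron = neuron, learning = learning
    ),
    class = "experiment_config"
  )
}

#' Generate a Poisson spike train on the 1-ms grid
#'
#' Independent Bernoulli draws per step with success probability
#' `rate_hz * dt / 1000`, the discretized equivalent of exponentially
#' distributed interspike intervals. Draws come from the current RNG
#' state, so seed with `set.seed()` for reproducibility.
#'
#' @param rate_hz Mean firing rate (Hz); `rate_hz * dt / 1000` must be
#'   below 1.
#' @param length_ms Train duration (ms).
#' @param dt Step (ms), default 1.
#' @return A `spike_train`.
#' @export
generate_poisson_train <- function(rate_hz, length_ms, dt = 1) {
  p <- rate_hz * dt / 1000
  if (p >= 1) stop("`rate_hz * dt` implies >= 1 spike per step", call. = FALSE)
  if (p < 0) stop("`rate_hz` must be non-negative", call. = FALSE)
  n_steps <- as.integer(length_ms / dt)
  spike_train(which(stats::runif(n_steps) < p) - 1L, length_ms = length_ms)
}

#' XOR reference train from two input trains
#'
#' Both inputs are binned at `window_ms`; the target bit sequence is the
#' bitwise XOR of the binned inputs. To realize the target as a 1-ms
#' spike train, one spike is placed at the center of each high bin, so
#' binning the reference recovers the target exactly.
#'
#' @param inputA,inputB `spike_train`s of equal length.
#' @param window_ms Binning window W (ms).
#' @return A list with `reference` (the `spike_train` g) and `binned`
#'   (the target `binned_train` G).
#' @export
xor_reference <- function(inputA, inputB, window_ms) {
  if (inputA$length_ms != inputB$length_ms) {
    stop("input spike trains must have equal length", call. = FALSE)
  }
  FA <- bin_train(inputA, window_ms)
  FB <- bin_train(inputB, window_ms)
  G <- binned_train(as.integer(xor(FA$bits == 1L, FB$bits == 1L)), window_ms)
  high <- which(G$bits == 1L) - 1L
  g <- spike_train(high * window_ms + window_ms %/% 2L,
                   length_ms = inputA$length_ms)
  list(reference = g, binned = G)
}

#' Run the full episodic training loop
#'
#' Executes `n_episodes` independent trials. Per episode: two fresh
#' Poisson input trains are taken from the pre-generated corpus (2 *
#' `n_episodes` trains drawn up front from the input substream and split
#' into two subsets, one per input neuron, consumed in episode order --
#' no train is ever re-presented), the XOR reference is built, the network
#' is simulated, the binned output `F` is compared to the target `G` (van
#' Rossum distance, reward, maximum cross-correlation, hit rates), and the
#' learning step updates the eligible synapse parameters.
#'
#' The whole run is a pure function of its configuration, seeds included.
#'
#' @param cfg An `experiment_config`.
#' @param progress Print a short progress note every 100 episodes.
#' @return An object of class `xor_training`: a list with
#' \describe{
#'   \item{episodes}{tibble, one row per episode: `episode`, `distance`,
#'     `reward`, `crosscorr`, `hit_rate_raw`, `hit_rate_binned`, `delta`,
#'     `n_output_spikes`, `n_reference_spikes`.}
#'   \item{parameters}{long tibble of eligible-synapse parameter values
#'     per episode (`episode`, `syn_id`, `inhibitory`, `parameter`,
#'     `value`), snapshot taken after the episode's update.}
#'   \item{strength}{long tibble of per-episode time-averaged dynamic
#'     strength `<S(t)>` for every synapse (`episode`, `syn_id`, `layer`,
#'     `inhibitory`, `trained`, `mean_S`).}
#'   \item{network}{the trained `tm_network`.}
#'   \item{config}{the configuration.}
#'   \item{manifest}{reproducibility manifest, see [run_manifest()].}
#' }
#' @examples
#' \donttest{
#' cfg <- experiment_config(n_hidden = 5, n_episodes = 20, seed = 1)
#' fit <- run_training(cfg)
#' glance(fit)
#' }
#' @export
run_training <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  ne <- cfg$n_episodes

  withr_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    code()
  }

  network <- withr_seed(cfg$seed_topology, function() {
    build_network(
      cfg$n_hidden,
      U_SE = cfg$U_SE_init, tau_rec = cfg$tau_rec_init,
      tau_fac = cfg$tau_fac_init,
      A = cfg$A, neuron = cfg$neuron,
      literal_params = cfg$literal_params
    )
  })

  corpus <- withr_seed(cfg$seed_inputs, function() {
    lapply(seq_len(2L * ne), function(i) {
      generate_poisson_train(cfg$input_rate_hz, cfg$episode_ms, cfg$dt)
    })
  })
  inputs_a <- corpus[seq_len(ne)]
  inputs_b <- corpus[ne + seq_len(ne)]

  syn <- network$synapses
  trained <- syn$layer == "ih"
  elig <- which(trained)
  n_elig <- length(elig)
  lc <- cfg$learning

  records <- vector("list", ne)
  param_snaps <- vector("list", ne)
  strength <- vector("list", ne)
  reward_state <- list(previous = NULL, current = NULL)

  for (ep in seq_len(ne)) {
    a <- inputs_a[[ep]]
    b <- inputs_b[[ep]]
    ref <- xor_reference(a, b, cfg$window_ms)
    sim <- simulate_episode(network, list(a, b), dt = cfg$dt)
    f_binned <- bin_train(sim$output, cfg$window_ms)
    d <- van_rossum_distance(f_binned, ref$binned, tau_c = cfg$tau_c)
    rwd <- compute_reward(d, lc$alpha)
    x <- suppressWarnings(
      max_crosscorr(f_binned, ref$binned, sigma_bins = cfg$sigma_bins)
    )
    reward_state$current <- rwd
    h <- hebbian_attribution(
      network,
      list(bin_train(a, cfg$window_ms), bin_train(b, cfg$window_ms)),
      sim$hidden_bits, ref$binned,
      attribution = lc$attribution
    )
    step <- learning_step(reward_state, network, lc, attribution = h)
    network <- step$network
    reward_state <- step$reward_state

    records[[ep]] <- tibble::tibble(
      episode = ep, distance = d, reward = rwd, crosscorr = x,
      hit_rate_raw = hit_rate(sim$output, ref$reference),
      hit_rate_binned = hit_rate(f_binned, ref$binned),
      delta = step$delta,
      n_output_spikes = n_spikes(sim$output),
      n_reference_spikes = n_spikes(ref$reference)
    )
    es <- network$synapses[elig, ]
    param_snaps[[ep]] <- tibble::tibble(
      episode = ep,
      syn_id = rep(es$syn_id, 3L),
      inhibitory = rep(es$inhibitory, 3L),
      parameter = rep(c("U_SE", "tau_rec", "tau_fac"), each = n_elig),
      value = c(es$U_SE, es$tau_rec, es$tau_fac)
    )
    strength[[ep]] <- tibble::tibble(
      episode = ep, syn_id = syn$syn_id, layer = syn$layer,
      inhibitory = syn$inhibitory, trained = trained,
      mean_S = sim$mean_S
    )
    if (progress && ep %% 100 == 0) {
      message(sprintf("episode %d/%d: D = %.2f, X = %.3f", ep, ne, d, x))
    }
  }

  structure(
    list(
      episodes = dplyr::bind_rows(records),
      parameters = dplyr::bind_rows(param_snaps),
      strength = dplyr::bind_rows(strength),
      network = network,
      config = cfg,
      manifest = run_manifest(cfg)
    ),
    class = "xor_training"
  )
}

#' @export
print.xor_training <- function(x, ...) {
  cat(sprintf(
    "<xor_training> %d episodes, %d hidden neurons, W = %d ms, seed %d\n",
    nrow(x$episodes), x$config$n_hidden, x$config$window_ms, x$config$seed
  ))
  print(glance(x))
  invisible(x)
}

#' Summarize a training run
#'
#' Mean and SD of the performance measures over the final `last_k`
#' episodes, plus the dynamic-strength regime comparison: per synapse
#' group (trained/untrained x excitatory/inhibitory), the mean and SD of
#' the per-episode time-averaged strength `<S(t)>` over the first and
#' second halves of training.
#'
#' @param result An `xor_training` object (or its `episodes` tibble
#'   together with `strength`).
#' @param last_k Number of trailing episodes to average; default 50.
#' @return A list with `performance` (tibble: metric, mean, sd over the
#'   last `last_k` episodes) and `strength_shift` (tibble per synapse
#'   group: first-half and second-half mean/SD of `<S>` and their absolute
#'   difference in pooled-SD units).
#' @export
summarize_training <- function(result, last_k = 50) {
  stopifnot(inherits(result, "xor_training"))
  ep <- result$episodes
  if (nrow(ep) < last_k) {
    stop(sprintf("need at least %d episodes, have %d", last_k, nrow(ep)),
         call. = FALSE)
  }
  tail_ep <- dplyr::slice_tail(ep, n = last_k)
  performance <- tail_ep |>
    dplyr::select(dplyr::all_of(c(
      "distance", "crosscorr", "reward", "hit_rate_raw", "hit_rate_binned"
    ))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value),
      .groups = "drop"
    )

  half <- nrow(ep) %/% 2L
  strength_shift <- result$strength |>
    dplyr::mutate(phase = ifelse(.data$episode <= half, "first", "second")) |>
    dplyr::group_by(.data$trained, .data$inhibitory, .data$phase) |>
    dplyr::summarise(
      sd_S = stats::sd(.data$mean_S), mean_S = mean(.data$mean_S),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "phase",
                       values_from = c("mean_S", "sd_S")) |>
    dplyr::mutate(
      shift_sd_units = abs(.data$mean_S_second - .data$mean_S_first) /
        sqrt((.data$sd_S_first^2 + .data$sd_S_second^2) / 2)
    )

  list(performance = performance, strength_shift = strength_shift,
       last_k = last_k)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
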