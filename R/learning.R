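#' Learning hyperparameters
#'
#' Configuration of the reward-modulated Hebbian/anti-Hebbian rule that
#' tunes the hidden synaptic parameters. After every episode the reward
#' `Rwd = exp(-alpha * D)` is computed from the van Rossum distance `D`
#' between the binned output and reference sequences, the
#' temporal-difference error `delta = mu * (Rwd_prev - Rwd_curr)` is
#' formed, and every eligible synapse updates each trainable parameter `m`
#' multiplicatively: `m <- clip(m + sign_m * eta * m * delta)`.
#'
#' The printed update rule moves all parameters together with the sign of
#' `delta`; the Hebbian reading (facilitatory contributions strengthened,
#' depressive weakened when performance improves) requires opposed
#' directions for facilitation- and depression-controlling parameters. The
#' per-parameter `signs` table encodes that reading: with the defaults
#' `U_SE = -1`, `tau_fac = -1`, `tau_rec = +1`, an improvement in reward
#' (`delta < 0`) raises `U_SE` and `tau_fac` and lowers `tau_rec`. The
#' table is exposed because the convention is a modelling choice.
#'
#' @param eta Learning rate, `|eta| < 1`; default 0.01.
#' @param mu Temporal-difference scaling factor; default 7.
#' @param alpha Reward exponent scale; default 0.01.
#' @param lambda_trace Trace decay; fixed at 1 (unscaled rewards).
#' @param trainable Character subset of `c("U_SE", "tau_rec", "tau_fac")`.
#'   `A` is never trainable.
#' @param signs Named numeric vector of update directions (+1/-1), one per
#'   trainable parameter.
#' @param bounds Named list of `c(lower, upper)` clip ranges.
#' @param flip_inhibitory If `TRUE`, inhibitory eligible synapses use the
#'   negated sign table.
#' @param attribution How the per-synapse Hebbian direction is derived
#'   from the episode's activity (see [hebbian_attribution()]):
#'   `"error"` (default; the sign of missed minus spurious induced
#'   spikes on the pathway), `"hit_false_alarm"` (sign of desired minus
#'   undesired induced spikes), `"hit_rejection"` (desired spikes
#'   strengthen, correct silences weaken, per presynaptically active
#'   bin), or `"none"` (no attribution: every eligible synapse shares
#'   the bare global error, the degenerate rule whose cumulative update
#'   telescopes to the net reward change).
#' @param td_coupling How the temporal-difference error enters the
#'   update. `"magnitude"` (default): the error sets the step size
#'   (`eta * m * |delta|`) and the direction comes from the Hebbian
#'   attribution and the sign table. `"signed"`: the literal product
#'   `sign_m * eta * m * delta * h`, in which the error's sign alternates
#'   the direction; its cumulative effect telescopes to the net reward
#'   change, so it cannot drive convergence and is kept for comparison.
#' @return A list of class `learning_config`.
#' @export
learning_config <- function(eta = 0.01, mu = 7, alpha = 0.01,
                            lambda_trace = 1,
                            trainable = c("U_SE", "tau_rec", "tau_fac"),
                            signs = c(U_SE = -1, tau_rec = 1, tau_fac = -1),
                            bounds = list(U_SE = c(0.01, 1),
                                          tau_rec = c(1, 1000),
                                          tau_fac = c(1, 1000)),
                            flip_inhibitory = FALSE,
                            attribution = c("error", "hit_false_alarm",
                                            "hit_rejection", "none"),
                            td_coupling = c("magnitude", "signed")) {
  attribution <- match.arg(attribution)
  td_coupling <- match.arg(td_coupling)
  if (abs(eta) >= 1) stop("|eta| must be < 1", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  if (mu <= 0) stop("`mu` must be positive", call. = FALSE)
  trainable <- match.arg(trainable, c("U_SE", "tau_rec", "tau_fac"),
                         several.ok = TRUE)
  if (!all(trainable %in% names(signs)) ||
      !all(trainable %in% names(bounds))) {
    stop("`signs` and `bounds` must cover every trainable parameter",
         call. = FALSE)
  }
  structure(
    list(eta = eta, mu = mu, alpha = alpha, lambda_trace = lambda_trace,
         trainable = trainable, signs = signs, bounds = bounds,
         flip_inhibitory = flip_inhibitory, attribution = attribution,
         td_coupling = td_coupling),
    class = "learning_config"
  )
}

#' Per-synapse Hebbian attribution of an episode's outcome
#'
#' The Hebbian reading of the update rule ties the direction of change to
#' the pairing of pre- and postsynaptic activity with the desired
#' behaviour: parameters of facilitatory mechanisms grow when a
#' presynaptic spike induces a desired postsynaptic spike (a correct
#' hit), and the process is flipped when no postsynaptic spike occurs and
#' none is expected. Desiredness is judged on the binning grid against
#' the reference sequence `G`.
#'
#' For the eligible synapse from input `i` to hidden neuron `j`, with
#' per-bin indicators `pre` (input `i` active), `post` (hidden `j`
#' active) and `G` (target high), write `hits = #[pre & post & G]`
#' (desired induced spikes), `fa = #[pre & post & !G]` (undesired induced
#' spikes), `miss = #[pre & !post & G]` (expected spikes that did not
#' occur) and `cr = #[pre & !post & !G]` (correct silences). Then:
#' \describe{
#'   \item{`"error"`}{`h = sign(miss - fa)`: facilitate a pathway that
#'     under-shoots its target, depress one that fires when it should
#'     not, and rest at the balance point. This error-correcting
#'     direction keeps working when the pathway is silent (a silent
#'     synapse facing expected spikes is pushed toward activity), which
#'     is what lets runs started from very small `U_SE` climb to the
#'     same operating point as runs started at the default.}
#'   \item{`"hit_false_alarm"`}{`h = sign(hits - fa)`, the pure
#'     Hebbian/anti-Hebbian direction of the pathway's realized
#'     activity; zero whenever the pathway is silent.}
#'   \item{`"hit_rejection"`}{`h = (hits - cr) / #[pre]`, the literal
#'     two-case narrative (desired induced spikes strengthen, correct
#'     silences weaken).}
#'   \item{`"none"`}{`h = 1` for every synapse.}
#' }
#' `h` lies in \[-1, 1\] and multiplies the shared temporal-difference
#' error in the parameter update, so the per-episode relative change
#' stays bounded by `eta * mu`.
#'
#' @param network A `tm_network`.
#' @param input_bins List of the two binned input trains
#'   (`binned_train`s or 0/1 vectors).
#' @param hidden_bits Steps-by-hidden logical/0-1 matrix of hidden spikes
#'   as returned by [simulate_episode()].
#' @param target The reference `binned_train` `G` (or 0/1 vector); the
#'   hidden activity is binned onto the same grid.
#' @param attribution Variant name, see [learning_config()].
#' @return Numeric vector, one attribution per eligible synapse (in
#'   `eligible_synapses()` order).
#' @export
hebbian_attribution <- function(network, input_bins, hidden_bits, target,
                                attribution = c("error", "hit_false_alarm",
                                                "hit_rejection", "none")) {
  attribution <- match.arg(attribution)
  idx <- eligible_synapses(network)
  if (attribution == "none") return(rep(1, length(idx)))
  bits <- function(x) if (inherits(x, "binned_train")) x$bits else as.integer(x)
  G <- bits(target) == 1L
  pre <- lapply(input_bins, function(x) bits(x) == 1L)
  nb <- length(G)
  # bin the hidden activity: a bin is high if the neuron spiked in it
  grp <- rep(seq_len(nb), each = nrow(hidden_bits) %/% nb)
  post <- apply(hidden_bits, 2, function(col) {
    as.logical(tapply(col, grp, any))
  })
  syn <- network$synapses[idx, ]
  vapply(seq_along(idx), function(k) {
    p <- pre[[syn$pre[k]]]
    q <- post[, syn$post[k]]
    fa <- sum(p & q & !G)
    switch(attribution,
      error = sign(sum(p & !q & G) - fa),
      hit_false_alarm = sign(sum(p & q & G) - fa),
      hit_rejection = {
        n_pre <- sum(p)
        if (n_pre == 0L) 0 else (sum(p & q & G) - sum(p & !q & !G)) / n_pre
      }
    )
  }, numeric(1))
}

#' Episodic reward from the spike-train distance
#'
#' `Rwd = exp(-alpha * D)` maps a distance in `[0, Inf)` to a
#' dimensionless reward in `(0, 1]`, with unit reward at zero distance.
#'
#' @param distance Non-negative van Rossum distance `D(F, G)`.
#' @param alpha Exponent scale, default 0.01.
#' @return Reward value(s) in (0, 1].
#' @export
compute_reward <- function(distance, alpha = 0.01) {
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  if (any(distance < 0)) stop("`distance` must be non-negative", call. = FALSE)
  exp(-alpha * distance)
}

#' Temporal-difference error between consecutive episode rewards
#'
#' `delta = mu * (Rwd_previous - Rwd_current)`. The sign carries the
#' direction information used by the parameter update: negative when the
#' reward improved.
#'
#' @param prev,curr Rewards in (0, 1].
#' @param mu Scaling factor matching the error to the parameter scale;
#'   default 7.
#' @return Signed error.
#' @export
td_error <- function(prev, curr, mu = 7) {
  mu * (prev - curr)
}

#' Synapses eligible for training
#'
#' Only the forward input-to-hidden synapses are updated by the learning
#' rule, excitatory and inhibitory alike; hidden-to-output synapses are
#' never eligible.
#'
#' @param network A `tm_network`.
#' @return Integer vector of eligible synapse row indices.
#' @export
eligible_synapses <- function(network) {
  which(network$synapses$layer == "ih")
}

#' Apply the multiplicative parameter update to synapse rows
#'
#' For each trainable parameter `m` of each supplied synapse:
#' `m <- clip(m + sign_m * eta * m * delta, bounds_m)`. The rule is
#' multiplicative in `m`, so a positive parameter stays positive and the
#' per-episode relative change is bounded by `eta * |delta|`. Values at a
#' bound are clipped, not an error. `A` is never modified.
#'
#' @param synapses Tibble of synapse rows (columns `U_SE`, `tau_rec`,
#'   `tau_fac`, `inhibitory`, ...), as in a `tm_network`.
#' @param delta Signed temporal-difference error.
#' @param cfg A `learning_config`.
#' @param attribution Per-row Hebbian attribution in \[-1, 1\] (recycled);
#'   default 1, the unattributed rule.
#' @return The tibble with updated parameter columns.
#' @export
update_parameters <- function(synapses, delta, cfg, attribution = 1) {
  if (!is.finite(delta)) stop("`delta` must be finite", call. = FALSE)
  attribution <- rep_len(attribution, nrow(synapses))
  for (m in cfg$trainable) {
    s <- rep(cfg$signs[[m]], nrow(synapses))
    if (isTRUE(cfg$flip_inhibitory)) s[synapses$inhibitory] <- -s[synapses$inhibitory]
    v <- synapses[[m]] + s * cfg$eta * synapses[[m]] * delta * attribution
    synapses[[m]] <- pmin(pmax(v, cfg$bounds[[m]][1]), cfg$bounds[[m]][2])
  }
  synapses
}

#' One episodic learning step
#'
#' Rolls the reward state and, when a previous reward exists, applies the
#' temporal-difference update to every eligible synapse. On the first
#' episode no error is defined, so no update occurs and the reward is only
#' recorded.
#'
#' @param reward_state List with `previous` (reward or `NULL`) and
#'   `current` (this episode's reward).
#' @param network A `tm_network`.
#' @param cfg A `learning_config`.
#' @param attribution Optional per-eligible-synapse Hebbian attribution
#'   vector from [hebbian_attribution()]; default 1 for every synapse.
#' @return A list: updated `network`, the applied `delta` (`NA` on the
#'   first episode), the rolled `reward_state`, and `log`, a tibble of
#'   per-parameter old/new values for the eligible synapses (empty on the
#'   first episode).
#' @export
learning_step <- function(reward_state, network, cfg, attribution = 1) {
  empty_log <- tibble::tibble(
    syn_id = integer(), parameter = character(),
    old = numeric(), new = numeric(), delta = numeric()
  )
  if (is.null(reward_state$previous)) {
    return(list(
      network = network, delta = NA_real_,
      reward_state = list(previous = reward_state$current, current = NULL),
      log = empty_log
    ))
  }
  delta <- td_error(reward_state$previous, reward_state$current, cfg$mu)
  # magnitude coupling: the TD error sets the step size, the attribution
  # and sign table set the direction (an improvement, delta < 0, moves
  # positively attributed synapses toward more facilitation)
  step <- if (cfg$td_coupling == "magnitude") -abs(delta) else delta
  idx <- eligible_synapses(network)
  old <- network$synapses[idx, ]
  new <- update_parameters(old, step, cfg, attribution)
  network$synapses[idx, ] <- new
  log <- purrr::map_dfr(cfg$trainable, function(m) {
    tibble::tibble(
      syn_id = old$syn_id, parameter = m,
      old = old[[m]], new = new[[m]], delta = delta
    )
  })
  list(
    network = network, delta = delta,
    reward_state = list(previous = reward_state$current, current = NULL),
    log = log
  )
}
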