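#' Tsodyks-Markram dynamic synapse parameters
#'
#' The short-term-plasticity model tracks two state variables per synapse:
#' `r`, the fraction of the neurotransmitter pool available for release
#' (depression, recovering with time constant `tau_rec`), and `u`, the
#' utilization fraction (facilitation, relaxing toward its baseline `U_SE`
#' with time constant `tau_fac`). The postsynaptic drive of one presynaptic
#' spike is `A * u * r` evaluated just after the facilitation jump; `A` is
#' the spike-timing-independent synaptic weight and is negative for
#' inhibitory synapses.
#'
#' @param U_SE Utilization increment, in (0, 1].
#' @param tau_rec Pool recovery time constant (ms), > 0.
#' @param tau_fac Facilitation relaxation time constant (ms), > 0.
#' @param A Baseline synaptic output (signed; negative = inhibitory).
#'
#' @return A list of class `tm_params`. All fields may be vectors of a
#'   common length, in which case they describe a population of synapses.
#' @examples
#' p <- tm_params()
#' s <- tm_state(p)
#' decay_synapse(s, p, dt = 10)
#' @export
tm_params <- function(U_SE = 0.5, tau_rec = 100, tau_fac = 50, A = 1) {
  if (any(U_SE <= 0 | U_SE > 1)) {
    stop("`U_SE` must lie in (0, 1]", call. = FALSE)
  }
  if (any(tau_rec <= 0) || any(tau_fac <= 0)) {
    stop("synaptic time constants must be positive", call. = FALSE)
  }
  structure(
    list(U_SE = U_SE, tau_rec = tau_rec, tau_fac = tau_fac, A = A),
    class = "tm_params"
  )
}

#' @rdname tm_params
#' @param params A `tm_params` object.
#' @return `tm_state()` returns the resting state: full pool (`r = 1`) and
#'   baseline utilization (`u = U_SE`).
#' @export
tm_state <- function(params) {
  structure(
    list(r = rep(1, length(params$U_SE)), u = params$U_SE),
    class = "tm_state"
  )
}

#' Relax synapse state between spikes
#'
#' Between presynaptic spikes the pool recovers toward 1 and utilization
#' relaxes toward its baseline, each as a first-order linear ODE. The update
#' is the exact exponential solution over the step, so there is no
#' integration error at any step size:
#' `r' = 1 - (1 - r) exp(-dt/tau_rec)`,
#' `u' = U_SE + (u - U_SE) exp(-dt/tau_fac)`.
#'
#' @param state A `tm_state` (fields `r`, `u`; possibly vectors).
#' @param params Matching `tm_params`.
#' @param dt Step length (ms), > 0.
#' @return The relaxed `tm_state`.
#' @export
decay_synapse <- function(state, params, dt) {
  if (any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  if (any(params$tau_rec <= 0) || any(params$tau_fac <= 0)) {
    stop("synaptic time constants must be positive", call. = FALSE)
  }
  state$r <- 1 - (1 - state$r) * exp(-dt / params$tau_rec)
  state$u <- params$U_SE + (state$u - params$U_SE) * exp(-dt / params$tau_fac)
  state
}

#' Apply one presynaptic spike to a synapse
#'
#' At a presynaptic spike utilization first jumps,
#' `u+ = u + U_SE * (1 - u)` (which keeps `u < 1` for `U_SE <= 1`), the
#' released fraction is `u+ * r`, and the pool is depressed by that amount.
#' The returned `release` is the dynamic part of the response; the
#' postsynaptic potential contribution is `A * release`.
#'
#' @inheritParams decay_synapse
#' @return A list with the updated `state` and the `release` vector.
#' @export
spike_synapse <- function(state, params) {
  u_plus <- state$u + params$U_SE * (1 - state$u)
  release <- u_plus * state$r
  state$u <- u_plus
  state$r <- state$r - release
  list(state = state, release = release)
}

#' Dynamic synaptic strength
#'
#' `S(t) = r(t) * u(t)`, the spike-timing-dependent part of the synaptic
#' response. Bounded in \[0, 1).
#'
#' @param state A `tm_state`.
#' @return Numeric vector of strengths.
#' @export
synaptic_strength <- function(state) {
  state$r * state$u
}
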