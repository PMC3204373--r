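#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane dynamics follow `tau_V dV/dt = V_rest - V + EPSP(t)`. A spike is
#' emitted when `V >= V_th`; the potential then resets to `V_rest` and the
#' neuron is clamped there for an absolute refractory period `tau_refr`.
#'
#' @param tau_V Membrane time constant (ms), default 20.
#' @param V_rest Resting potential (mV), default 0.
#' @param V_th Firing threshold (mV), default 50.
#' @param tau_refr Absolute refractory period (ms), default 2.
#' @return A list of class `liaf_params`.
#' @export
liaf_params <- function(tau_V = 20, V_rest = 0, V_th = 50, tau_refr = 2) {
  if (tau_V <= 0) stop("`tau_V` must be positive", call. = FALSE)
  if (tau_refr < 0) stop("`tau_refr` must be non-negative", call. = FALSE)
  if (V_th <= V_rest) stop("`V_th` must exceed `V_rest`", call. = FALSE)
  structure(
    list(tau_V = tau_V, V_rest = V_rest, V_th = V_th, tau_refr = tau_refr),
    class = "liaf_params"
  )
}

#' @rdname liaf_params
#' @param params A `liaf_params` object.
#' @param n Number of neurons sharing these parameters.
#' @return `liaf_state()` returns the resting state: `V = V_rest`, no
#'   refractory time remaining. Fields are length-`n` vectors.
#' @export
liaf_state <- function(params, n = 1L) {
  structure(
    list(V = rep(params$V_rest, n), refr = numeric(n)),
    class = "liaf_state"
  )
}

#' Advance LIaF neurons one time step
#'
#' The membrane equation is integrated exactly over the step assuming the
#' total synaptic drive `epsp_total` is constant across it:
#' `V' = V_rest + (V - V_rest) e^(-dt/tau_V) + epsp_total (1 - e^(-dt/tau_V))`.
#' Neurons inside their refractory window stay clamped at `V_rest`, cannot
#' spike, and have their refractory clock decremented. A threshold crossing
#' resets `V` to `V_rest` and arms the refractory clock, so `V` never sits
#' at or above `V_th` at a step boundary.
#'
#' @param state A `liaf_state` (vector fields `V`, `refr`).
#' @param params A `liaf_params` object.
#' @param epsp_total Total synaptic drive per neuron over this step.
#' @param dt Step length (ms), > 0.
#' @return A list with the updated `state` and a logical `spiked` vector.
#' @export
step_neuron <- function(state, params, epsp_total, dt) {
  if (any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  V <- state$V
  refr <- state$refr
  in_refr <- refr > 0
  k <- exp(-dt / params$tau_V)
  V <- params$V_rest + (V - params$V_rest) * k + epsp_total * (1 - k)
  V[in_refr] <- params$V_rest
  refr[in_refr] <- pmax(0, refr[in_refr] - dt)
  spiked <- !in_refr & V >= params$V_th
  V[spiked] <- params$V_rest
  refr[spiked] <- params$tau_refr
  state$V <- V
  state$refr <- refr
  list(state = state, spiked = spiked)
}
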