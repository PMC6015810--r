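#' Create an empty trace state
#'
#' Presynaptic traces C (one per synapse; meaningful for plastic ones)
#' and postsynaptic traces D (one per neuron), all starting at zero.
#'
#' @param network a `spiking_network`.
#' @return `list(C = numeric, D = numeric)`.
#' @export
new_trace_state <- function(network) {
  list(C = numeric(nrow(network$syn)), D = numeric(length(network$is_input)))
}

#' Exponential decay of STDP traces
#'
#' `C <- C * exp(-dt/tau_c)`, `D <- D * exp(-dt/tau_d)`. Zero is a fixed
#' point, so traces decay toward 0 in the absence of spikes and never
#' leave \[0, 1\].
#'
#' @param traces `list(C, D)`.
#' @param dt elapsed time (ms).
#' @param params a [plasticity_params()].
#' @return Updated traces.
#' @export
decay_traces <- function(traces, dt, params) {
  stopifnot(dt > 0)
  traces$C <- traces$C * exp(-dt / params$tau_c)
  traces$D <- traces$D * exp(-dt / params$tau_d)
  traces
}

#' STDP update at presynaptic spike arrival
#'
#' Invoked when presynaptic spikes *arrive* (emission time plus the
#' synapse's axonal delay), not when they are emitted. Long-term
#' depression is applied first using the current postsynaptic trace:
#' `w <- w - rho * D_post * w`; the presynaptic trace is then driven:
#' `C <- C + alpha_c * (1 - C)`. The multiplicative form keeps weights in
#' \[0, 1\].
#'
#' @param syn_ids integer indices of the synapses receiving an arrival.
#' @param traces `list(C, D)` (current values, already decayed to now).
#' @param weights per-synapse weight vector.
#' @param params a [plasticity_params()].
#' @param syn_post integer vector: postsynaptic neuron per synapse (the
#'   network's `syn$post` column).
#' @return `list(traces, weights)`.
#' @export
on_presynaptic_arrival <- function(syn_ids, traces, weights, params,
                                   syn_post) {
  p <- syn_post[syn_ids]
  w <- weights[syn_ids]
  weights[syn_ids] <- w - params$rho * traces$D[p] * w
  traces$C[syn_ids] <- traces$C[syn_ids] +
    params$alpha_c * (1 - traces$C[syn_ids])
  list(traces = traces, weights = weights)
}

#' STDP update at a postsynaptic spike
#'
#' Long-term potentiation is applied first to every plastic afferent
#' synapse using the current presynaptic traces:
#' `w <- w + rho * C * (1 - w)`; the postsynaptic trace is then driven:
#' `D <- D + alpha_d * (1 - D)`.
#'
#' @param neurons indices of neurons that spiked.
#' @param traces `list(C, D)`.
#' @param weights per-synapse weight vector.
#' @param network the `spiking_network` (for the afferent lookup).
#' @param params a [plasticity_params()].
#' @return `list(traces, weights)`.
#' @export
on_postsynaptic_spike <- function(neurons, traces, weights, network, params) {
  syn <- network$syn
  aff <- which(syn$plastic & syn$post %in% neurons)
  if (length(aff)) {
    w <- weights[aff]
    weights[aff] <- w + params$rho * traces$C[aff] * (1 - w)
  }
  traces$D[neurons] <- traces$D[neurons] +
    params$alpha_d * (1 - traces$D[neurons])
  list(traces = traces, weights = weights)
}
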