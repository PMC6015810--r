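#' Neuron class parameters
#'
#' Membrane parameters for one class of conductance-based leaky
#' integrate-and-fire (LIF) neurons. The membrane time constant is derived
#' as `tau_m = C_m / g_0` (pF / nS = ms, keeping the membrane equation
#' dimensionally closed in mV/ms/nS/pF units).
#'
#' @param C_m somatic capacitance (pF).
#' @param g_0 somatic leakage conductance (nS).
#' @param V_0 resting potential (mV).
#' @param theta firing threshold (mV); must exceed `V_0`.
#' @param V_H after-spike hyperpolarization potential (mV); at most `theta`.
#' @param tau_R absolute refractory period (ms).
#' @param class_label `"excitatory"` or `"inhibitory"`.
#' @return An object of class `neuron_class_params` (a named list with the
#'   fields above plus the derived `tau_m`).
#' @examples
#' ex <- neuron_class_params(C_m = 500, g_0 = 25, V_0 = -74,
#'                           theta = -53, V_H = -57, tau_R = 2,
#'                           class_label = "excitatory")
#' ex$tau_m  # 20 ms
#' @export
neuron_class_params <- function(C_m, g_0, V_0, theta, V_H, tau_R,
                                class_label = c("excitatory", "inhibitory")) {
  class_label <- match.arg(class_label)
  stopifnot(C_m > 0, g_0 > 0, tau_R > 0)
  if (theta <= V_0) stop("firing threshold must exceed the resting potential")
  if (V_H > theta) stop("after-spike potential must not exceed the threshold")
  structure(
    list(C_m = C_m, g_0 = g_0, tau_m = C_m / g_0, V_0 = V_0,
         theta = theta, V_H = V_H, tau_R = tau_R, class_label = class_label),
    class = "neuron_class_params")
}

#' Default LIF cell parameters
#'
#' The excitatory and inhibitory cellular parameter sets used throughout
#' the model: capacitance 500/214 pF, leak 25/18 nS, rest -74/-82 mV,
#' threshold -53 mV, reset -57/-58 mV, refractory period 2 ms. The
#' inhibitory membrane time constant derived from C_m/g_0 is 214/18 =
#' 11.89 ms, within ~1% of the conventionally quoted 12 ms; the derived
#' value is the one used.
#'
#' @return Named list with elements `excitatory` and `inhibitory`, each a
#'   [neuron_class_params()] object.
#' @export
default_neuron_params <- function() {
  list(
    excitatory = neuron_class_params(500, 25, -74, -53, -57, 2, "excitatory"),
    inhibitory = neuron_class_params(214, 18, -82, -53, -58, 2, "inhibitory"))
}

#' Synapse class parameters
#'
#' Shared parameters for one class of conductance-based synapses. A spike
#' arriving on a synapse of this class increments the synaptic conductance
#' by `g_scale * weight` nS (the biological scaling constant multiplied by
#' the dimensionless efficacy in \[0, 1\]); the conductance then decays
#' exponentially with time constant `tau_g` toward zero.
#'
#' @param name class label, e.g. `"EfE"`, `"IlE"`.
#' @param tau_g conductance decay time constant (ms).
#' @param V_rev reversal potential (mV); 0 for excitatory, -70 inhibitory.
#' @param g_scale conductance scaling bound (nS): the jump produced by a
#'   spike on a synapse with efficacy 1.
#' @param plastic logical; whether synapses of this class are modified by
#'   STDP.
#' @return An object of class `synapse_class_params`.
#' @export
synapse_class_params <- function(name, tau_g, V_rev, g_scale, plastic) {
  stopifnot(tau_g > 0, g_scale >= 0, is.logical(plastic))
  structure(list(name = name, tau_g = tau_g, V_rev = V_rev,
                 g_scale = g_scale, plastic = plastic),
            class = "synapse_class_params")
}

#' Default synapse classes for the four-layer architecture
#'
#' GfE: retina/Gabor-to-layer-1 feedforward (bound 0.4 nS). EfE/EbE/ElE:
#' excitatory-to-excitatory feedforward/feedback/lateral (1.6 nS), all
#' plastic with a 150 ms decay constant. ElI: excitatory onto inhibitory
#' (40 nS, 2 ms). IlE: inhibitory onto excitatory (80 nS, 5 ms, reversal
#' -70 mV). The two interneuron loops are non-plastic.
#'
#' @return Named list of [synapse_class_params()] objects.
#' @export
default_synapse_classes <- function() {
  list(
    GfE = synapse_class_params("GfE", 150, 0, 0.4, TRUE),
    EfE = synapse_class_params("EfE", 150, 0, 1.6, TRUE),
    EbE = synapse_class_params("EbE", 150, 0, 1.6, TRUE),
    ElE = synapse_class_params("ElE", 150, 0, 1.6, TRUE),
    ElI = synapse_class_params("ElI", 2, 0, 40, FALSE),
    IlE = synapse_class_params("IlE", 5, -70, 80, FALSE))
}

#' STDP (trace plasticity) parameters
#'
#' Trace-based spike-timing-dependent plasticity. A presynaptic trace C
#' per plastic synapse tracks recently *arrived* presynaptic spikes
#' (arrival = emission + axonal delay); a postsynaptic trace D per neuron
#' tracks recent postsynaptic spikes. On a postsynaptic spike every plastic
#' afferent is potentiated by `rho * C * (1 - w)` (LTP); on a presynaptic
#' arrival the synapse is depressed by `rho * D * w` (LTD). The
#' multiplicative soft bounds keep weights in \[0, 1\]. Traces are driven
#' by the saturating update `x <- x + alpha * (1 - x)` and decay
#' exponentially with their time constants, so they also stay in \[0, 1\].
#'
#' @param alpha_c,alpha_d trace increments in \[0, 1\] (default 0.5).
#' @param tau_c,tau_d trace decay time constants (ms).
#' @param rho learning rate (default 0.1).
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(alpha_c = 0.5, alpha_d = 0.5,
                              tau_c = 5, tau_d = 5, rho = 0.1) {
  stopifnot(alpha_c >= 0, alpha_c <= 1, alpha_d >= 0, alpha_d <= 1,
            tau_c > 0, tau_d > 0, rho > 0)
  structure(list(alpha_c = alpha_c, alpha_d = alpha_d,
                 tau_c = tau_c, tau_d = tau_d, rho = rho),
            class = "plasticity_params")
}

#' Maximum stimulus information for n stimuli
#'
#' The ceiling on the stimulus-specific information a single cell (or
#' spike-pair) can carry: `log2(n)` bits for `n` equiprobable stimuli.
#'
#' @param n_stimuli number of stimuli.
#' @return bits.
#' @examples
#' max_information(3)  # 1.585 bits
#' @export
max_information <- function(n_stimuli) {
  stopifnot(n_stimuli >= 1)
  log2(n_stimuli)
}
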