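# Tiny fixture networks built in code.

# n_in input units all projecting to one LIF neuron
single_neuron_net <- function(weight = 1, delay = 1, g_scale = 300,
                              tau_g = 2, n_in = 1, plastic = FALSE) {
  np <- default_neuron_params()$excitatory
  syn <- connection_group(pre = seq_len(n_in), post = rep(n_in + 1L, n_in),
                          weight = rep(weight, n_in),
                          delay_ms = rep(delay, n_in),
                          class_id = 1L, plastic = plastic)
  polybind:::new_spiking_network(
    is_input = c(rep(TRUE, n_in), FALSE),
    layer = c(rep(0L, n_in), 1L),
    nclass = c(rep(0L, n_in), 1L), pos = NULL,
    neuron_params = list(np),
    syn_classes = list(synapse_class_params("drive", tau_g, 0, g_scale,
                                            plastic)),
    syn = syn)
}

# random feedforward net: n_in inputs -> n_sim neurons, dense-ish wiring
random_small_net <- function(seed, n_in = 4, n_sim = 5, p = 0.6,
                             plastic = TRUE, g_scale = 40, tau_g = 5) {
  set.seed(seed)
  np <- default_neuron_params()$excitatory
  pre <- integer(); post <- integer()
  for (i in seq_len(n_in)) for (j in seq_len(n_sim))
    if (runif(1) < p) { pre <- c(pre, i); post <- c(post, n_in + j) }
  # some recurrent connections among simulated neurons
  for (i in seq_len(n_sim)) for (j in seq_len(n_sim))
    if (i != j && runif(1) < 0.3) {
      pre <- c(pre, n_in + i); post <- c(post, n_in + j)
    }
  n <- length(pre)
  syn <- connection_group(pre, post, runif(n), runif(n, 0.5, 6), 1L,
                          plastic)
  polybind:::new_spiking_network(
    is_input = c(rep(TRUE, n_in), rep(FALSE, n_sim)),
    layer = c(rep(0L, n_in), rep(1L, n_sim)),
    nclass = c(rep(0L, n_in), rep(1L, n_sim)), pos = NULL,
    neuron_params = list(np),
    syn_classes = list(synapse_class_params("EfE", tau_g, 0, g_scale,
                                            plastic)),
    syn = syn)
}

# random poisson input record for a set of input units
random_inputs <- function(seed, n_in, rate_hz, duration) {
  generate_poisson_trains(make_flat_stimulus(n_in, rate_hz), duration, seed)
}

# analytic LIF helpers (independent oracles)
lif_steady_state <- function(np, g, v_rev = 0) {
  (np$g_0 * np$V_0 + g * v_rev) / (np$g_0 + g)
}
lif_isi <- function(np, g, v_rev = 0) {
  vss <- lif_steady_state(np, g, v_rev)
  tau_eff <- np$C_m / (np$g_0 + g)
  np$tau_R + tau_eff * log((vss - np$V_H) / (vss - np$theta))
}
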