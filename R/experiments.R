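#' Derive a child seed from the master seed
#'
#' Deterministic counter scheme: each (role, index) pair maps to its own
#' child seed, so adding trials or phases never perturbs the seeds of
#' earlier ones. Roles: 1 wiring, 2 test transforms, 3 training
#' presentations, 4 auxiliary.
#'
#' @param master master seed (integer).
#' @param role integer role code.
#' @param index integer counter within the role.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, role, index = 0) {
  m <- 2147483629
  as.integer((as.numeric(master) * 1000003 + role * 10007 + index) %% m + 1)
}

collect_spikes <- function(res, trial) {
  if (nrow(res$spikes) == 0)
    return(data.frame(trial = integer(), neuron = integer(),
                      time = numeric()))
  data.frame(trial = trial, neuron = res$spikes$neuron,
             time = res$spikes$time)
}

#' Two-layer polychronization experiment
#'
#' The full protocol of the two-layer model: 10 pre-training test trials
#' (independent Poisson realizations of the flat 50 Hz stimulus, STDP
#' off), 10 training presentations (STDP on; trace time constants
#' `tau_c` = 100 ms, `tau_d` = 150 ms, learning rate 0.1), then 10
#' post-training test trials re-using the pre-training Poisson seeds so
#' pre/post comparisons are paired. Membrane state, conductances and
#' traces are reset between presentations; weights persist. First-spike
#' statistics are computed per layer, pre and post, restricted to
#' neurons responding on every test trial.
#'
#' @param seed master seed.
#' @param n_per_layer neurons per layer (reference 1000).
#' @param delay_12 layer-1 to layer-2 delay range (ms); `c(1, 1)` gives
#'   the synchrony control.
#' @param n_test,n_train number of test trials / training presentations.
#' @param duration presentation length (ms).
#' @param dt Euler step (ms).
#' @param rate input firing rate (Hz).
#' @param tau_c,tau_d,rho STDP parameters for training.
#' @param w_init_max initial-weight bound (see [build_two_layer()]).
#' @return A `polybind_run` list: `network` (trained), `records`
#'   (`pre`/`post` spike records with trial column), `stats`
#'   (first-spike statistics per phase and layer), `layers` (id ranges),
#'   `config`.
#' @export
run_two_layer_polychronization <- function(seed, n_per_layer = 1000,
                                           delay_12 = c(1, 30),
                                           n_test = 10, n_train = 10,
                                           duration = 200, dt = 0.02,
                                           rate = 50, tau_c = 100,
                                           tau_d = 150, rho = 0.1,
                                           w_init_max = 0.05) {
  net <- build_two_layer(derive_seed(seed, 1), n_per_layer,
                         delay_12 = delay_12, w_init_max = w_init_max)
  flat <- make_flat_stimulus(n_per_layer, rate)
  plast <- plasticity_params(tau_c = tau_c, tau_d = tau_d, rho = rho)
  test_phase <- function(network) {
    recs <- lapply(seq_len(n_test), function(i) {
      tr <- generate_poisson_trains(flat, duration, derive_seed(seed, 2, i))
      collect_spikes(run_trial(network, tr, duration, dt), i)
    })
    do.call(rbind, recs)
  }
  pre <- test_phase(net)
  for (j in seq_len(n_train)) {
    tr <- generate_poisson_trains(flat, duration, derive_seed(seed, 3, j))
    res <- run_trial(net, tr, duration, dt, plasticity = plast,
                     plasticity_on = TRUE)
    net$syn$weight <- res$weights
  }
  post <- test_phase(net)
  n <- n_per_layer
  layers <- list(l1 = n + seq_len(n), l2 = 2L * n + seq_len(n))
  layer_stats <- function(rec, ids) {
    sub <- rec[rec$neuron %in% ids, ]
    # a sentinel neuron present in every trial pins the trial universe to
    # the full test set even when some trials are silent in this layer
    fs <- suppressMessages(first_spike_statistics(
      rbind(sub, data.frame(trial = seq_len(n_test), neuron = -1L,
                            time = 0))))
    fs[fs$neuron != -1L, , drop = FALSE]
  }
  stats <- list(
    pre = lapply(layers, function(ids) layer_stats(pre, ids)),
    post = lapply(layers, function(ids) layer_stats(post, ids)))
  structure(list(network = net, records = list(pre = pre, post = post),
                 stats = stats, layers = layers,
                 config = list(seed = seed, n_per_layer = n_per_layer,
                               delay_12 = delay_12, n_test = n_test,
                               n_train = n_train, duration = duration,
                               dt = dt, rate = rate, tau_c = tau_c,
                               tau_d = tau_d, rho = rho,
                               w_init_max = w_init_max)),
            class = "polybind_run")
}

#' Synchrony control: uniform 1 ms layer-1 to layer-2 delays
#'
#' Identical protocol and seeds as [run_two_layer_polychronization()] but
#' with every layer-1 to layer-2 delay fixed at 1 ms; connectivity into
#' layer 1 is unchanged, so layer-1 results are directly comparable and
#' layer-2 differences isolate the effect of the delay distribution.
#'
#' @inheritParams run_two_layer_polychronization
#' @param ... passed to [run_two_layer_polychronization()].
#' @return A `polybind_run`.
#' @export
run_synchrony_control <- function(seed, ...) {
  run_two_layer_polychronization(seed, delay_12 = c(1, 1), ...)
}

#' Summary measures of a two-layer run
#'
#' Median first-spike standard deviation per layer and phase, all-trial
#' responder counts, and the across-neuron dispersion (standard
#' deviation) of post-training mean first-spike times -- the quantities
#' the polychronization and synchrony analyses compare.
#'
#' @param run a `polybind_run`.
#' @return Named list of scalars.
#' @export
summarize_two_layer <- function(run) {
  s <- run$stats
  list(
    median_sd_pre_l1 = stats::median(s$pre$l1$sd_ms),
    median_sd_pre_l2 = stats::median(s$pre$l2$sd_ms),
    median_sd_post_l1 = stats::median(s$post$l1$sd_ms),
    median_sd_post_l2 = stats::median(s$post$l2$sd_ms),
    responders_pre_l1 = nrow(s$pre$l1),
    responders_pre_l2 = nrow(s$pre$l2),
    responders_post_l1 = nrow(s$post$l1),
    responders_post_l2 = nrow(s$post$l2),
    dispersion_post_l2 = stats::sd(s$post$l2$mean_ms),
    dispersion_post_l1 = stats::sd(s$post$l1$mean_ms))
}

#' Four-layer training and information analysis
#'
#' Builds the four-layer architecture (optionally without feedback or
#' lateral excitatory pathways), trains it by presenting the three shape
#' stimuli (circle, heart, star) in turn with STDP on, then tests with
#' STDP off over independent Poisson transforms of each stimulus, and
#' computes the two output-layer information analyses: single-cell
#' rate-code information and spike-pair occurrence information, both
#' against the `log2(3)` ceiling.
#'
#' @param seed master seed.
#' @param grid_e excitatory grid side (desk default 16; reference 64).
#' @param retina retinal grid side (desk default `2*grid_e`).
#' @param feedback,lateral include EbE / ElE pathways (10 afferents when
#'   `TRUE`, 0 when `FALSE`).
#' @param n_sweeps training sweeps over the stimulus set (desk default
#'   10).
#' @param n_transforms test presentations per stimulus.
#' @param duration presentation length (ms; default 500 -- with the
#'   150 ms excitatory synaptic time constant, feedforward conductances
#'   need several hundred ms to integrate before the deep layers engage).
#' @param dt Euler step (ms; desk default 0.1).
#' @param tau_stdp STDP time constants `tau_c = tau_d` (ms). The default
#'   125 ms is the regime in which desk-scale training schedules converge
#'   (see the methods vignette); [run_stdp_timeconstant_sweep()] compares
#'   the full reference set \{5, 25, 125\} ms.
#' @param contacts_per_pair synaptic contacts per pre/post pair (M).
#' @param train logical; skip training for the untrained baseline.
#' @param info_bins response bins for the rate-code analysis.
#' @return A `polybind_run4` list: `network`, `records` (test spikes with
#'   stimulus/transform columns), `rate_info`, `pair_info`,
#'   `n_max_rate`, `n_max_pair` (cells/pairs at the information
#'   ceiling), `weight_history` (initial and final weights), `config`.
#' @export
run_four_layer_training <- function(seed, grid_e = 16,
                                    retina = 2 * grid_e,
                                    feedback = TRUE, lateral = TRUE,
                                    n_sweeps = 10, n_transforms = 10,
                                    duration = 500, dt = 0.1,
                                    tau_stdp = 125, contacts_per_pair = 1,
                                    train = TRUE, info_bins = 10) {
  net <- build_four_layer(derive_seed(seed, 1), grid_e = grid_e,
                          retina = retina,
                          fb_count = if (feedback) 10 else 0,
                          lat_count = if (lateral) 10 else 0,
                          contacts_per_pair = contacts_per_pair)
  stim_labels <- c("circle", "heart", "star")
  rate_maps <- lapply(stim_labels, function(lb)
    encode_image(make_shape_image(lb, retina)))
  names(rate_maps) <- stim_labels
  plast <- plasticity_params(tau_c = tau_stdp, tau_d = tau_stdp)
  w0 <- net$syn$weight
  if (train) {
    k <- 0
    for (sw in seq_len(n_sweeps)) for (s in seq_along(stim_labels)) {
      k <- k + 1
      tr <- generate_poisson_trains(rate_maps[[s]], duration,
                                    derive_seed(seed, 3, k))
      res <- run_trial(net, tr, duration, dt, plasticity = plast,
                       plasticity_on = TRUE)
      net$syn$weight <- res$weights
    }
  }
  # test with STDP off
  out_ids <- net$meta$idsE[[4]]
  recs <- list()
  for (s in seq_along(stim_labels)) for (tfm in seq_len(n_transforms)) {
    tr <- generate_poisson_trains(rate_maps[[s]], duration,
                                  derive_seed(seed, 2, (s - 1) * n_transforms + tfm))
    res <- run_trial(net, tr, duration, dt)
    sp <- res$spikes[res$spikes$neuron %in% out_ids, , drop = FALSE]
    recs[[length(recs) + 1L]] <-
      if (nrow(sp)) data.frame(stimulus = stim_labels[s], transform = tfm,
                               neuron = sp$neuron, time = sp$time)
      else data.frame(stimulus = character(), transform = integer(),
                      neuron = integer(), time = numeric())
  }
  records <- do.call(rbind, recs)
  # rate-code information over all output-layer excitatory cells
  grid <- expand.grid(cell = out_ids, stimulus = stim_labels,
                      transform = seq_len(n_transforms),
                      stringsAsFactors = FALSE)
  cnt <- if (nrow(records))
    stats::aggregate(time ~ neuron + stimulus + transform, records, length)
  else data.frame(neuron = integer(), stimulus = character(),
                  transform = integer(), time = integer())
  names(cnt) <- c("cell", "stimulus", "transform", "nsp")
  tab <- merge(grid, cnt, all.x = TRUE)
  tab$nsp[is.na(tab$nsp)] <- 0
  rt <- response_table(tab$cell, tab$stimulus, tab$transform,
                       tab$nsp / (duration / 1000))
  rate_info <- stimulus_specific_information(bin_responses(rt, info_bins))
  pair_tab <- build_pair_png_table(records, neurons = out_ids)
  pair_info <- pair_png_information(pair_tab)
  ceiling_bits <- max_information(length(stim_labels))
  tol <- 1e-6
  structure(list(
    network = net, records = records, rate_info = rate_info,
    pair_info = pair_info,
    n_max_rate = sum(rate_info$per_cell$max_info_bits >= ceiling_bits - tol),
    n_max_pair = sum(pair_info$max_info_bits >= ceiling_bits - tol),
    weight_history = list(initial = w0, final = net$syn$weight),
    config = list(seed = seed, grid_e = grid_e, retina = retina,
                  feedback = feedback, lateral = lateral,
                  n_sweeps = n_sweeps, n_transforms = n_transforms,
                  duration = duration, dt = dt, tau_stdp = tau_stdp,
                  contacts_per_pair = contacts_per_pair, train = train)),
    class = "polybind_run4")
}

#' STDP time-constant sweep
#'
#' Trains the four-layer model three times, identical in everything but
#' the STDP time constants `tau_c = tau_d` over the sweep grid, and
#' reports the number of spike-pair occurrences carrying maximal
#' stimulus information per setting. Short time constants preserve the
#' temporal precision of the plasticity rule and are expected to yield
#' the most stimulus-specific spike pairs.
#'
#' @param seed master seed (shared across settings, so runs differ only
#'   in the swept key).
#' @param taus sweep grid (ms).
#' @param ... passed to [run_four_layer_training()].
#' @return list with `runs` (per setting) and `counts` (named vector of
#'   maximal-information pair counts).
#' @export
run_stdp_timeconstant_sweep <- function(seed, taus = c(5, 25, 125), ...) {
  runs <- lapply(taus, function(tau)
    run_four_layer_training(seed, tau_stdp = tau, ...))
  names(runs) <- paste0("tau_", taus)
  counts <- vapply(runs, `[[`, numeric(1), "n_max_pair")
  list(runs = runs, counts = counts, taus = taus)
}

#' One- versus two-contact comparison
#'
#' Trains the four-layer model with one and with two synaptic contacts
#' per plastic pre/post pair (contact delays independently drawn from
#' \[0, 10\] ms) and reports, for the two-contact run, how the weight gap
#' between a pair's two contacts evolves: selective strengthening of one
#' delay shows up as the final gap exceeding the initial gap.
#'
#' @param seed master seed.
#' @param tau_stdp STDP time constants for this comparison (ms). Default
#'   5: contact selection is a temporal-precision effect -- the
#'   presynaptic trace must decay appreciably over the (up to 10 ms)
#'   difference between a pair's two contact delays, otherwise both
#'   contacts see the same trace statistics and their weights converge
#'   instead of diverging.
#' @param ... passed to [run_four_layer_training()].
#' @param driven_threshold a pair counts as strongly driven when the
#'   larger of its two final contact weights reaches this value.
#' @return list with `runs` (`M1`, `M2`), their maximal-pair counts, and
#'   `divergence` (data.frame of per-pair initial/final gaps for driven
#'   pairs) plus `frac_diverged`.
#' @export
run_multicontact_comparison <- function(seed, tau_stdp = 5, ...,
                                        driven_threshold = 0.5) {
  m1 <- run_four_layer_training(seed, contacts_per_pair = 1,
                                tau_stdp = tau_stdp, ...)
  m2 <- run_four_layer_training(seed, contacts_per_pair = 2,
                                tau_stdp = tau_stdp, ...)
  syn <- m2$network$syn
  key <- paste(syn$pre, syn$post, syn$class_id, sep = "_")
  dup <- syn$plastic & key %in% names(which(table(key) == 2))
  ix <- split(which(dup), key[dup])
  w0 <- m2$weight_history$initial
  w1 <- m2$weight_history$final
  gaps <- do.call(rbind, lapply(ix, function(id)
    data.frame(gap0 = abs(diff(w0[id])), gap1 = abs(diff(w1[id])),
               wmax = max(w1[id]))))
  driven <- gaps[gaps$wmax >= driven_threshold, , drop = FALSE]
  frac <- if (nrow(driven)) mean(driven$gap1 > driven$gap0) else NA_real_
  list(runs = list(M1 = m1, M2 = m2),
       counts = c(M1 = m1$n_max_pair, M2 = m2$n_max_pair),
       divergence = driven, frac_diverged = frac)
}
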