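#' Initialize simulation state for a network
#'
#' Per-neuron membrane potentials at rest, zero per-synapse conductances,
#' empty refractory clocks and a zero clock. Input units carry `NA`
#' membrane potentials (they only emit externally supplied spikes).
#'
#' @param network a `spiking_network`.
#' @return A `sim_state` list: `V` (mV), `refr_steps`, `g` (nS, per
#'   synapse), `t` (ms), `step` (integer step counter).
#' @export
new_sim_state <- function(network) {
  n <- length(network$is_input)
  V <- rep(NA_real_, n)
  for (cls in seq_along(network$neuron_params)) {
    sel <- network$nclass == cls
    V[sel] <- network$neuron_params[[cls]]$V_0
  }
  structure(list(V = V, refr_steps = integer(n),
                 g = numeric(nrow(network$syn)), t = 0, step = 0L),
            class = "sim_state")
}

#' One forward-Euler membrane step
#'
#' Advances every simulated neuron by one Euler step of
#' `tau_m dV/dt = (V_0 - V) + R I`, with `R = 1/g_0` and the synaptic
#' current `I_i = sum_j g_ij (V_rev(j) - V_i)` recomputed from the current
#' per-synapse conductances. Refractory neurons are clamped at `V_H` while
#' their countdown decrements. The clock advances by `dt`.
#'
#' @param state a `sim_state`.
#' @param network a `spiking_network`.
#' @param dt step size (ms).
#' @return Updated `sim_state`.
#' @export
integrate_step <- function(state, network, dt) {
  stopifnot(dt > 0)
  syn <- network$syn
  vrev <- vapply(network$syn_classes, `[[`, numeric(1), "V_rev")[syn$class_id]
  n <- length(state$V)
  # total current: sum over afferent synapses of g * (V_rev - V_post)
  gv <- state$g * vrev
  sum_gv <- unname(tapply_sum(gv, syn$post, n))
  sum_g <- unname(tapply_sum(state$g, syn$post, n))
  for (cls in seq_along(network$neuron_params)) {
    p <- network$neuron_params[[cls]]
    sel <- which(network$nclass == cls)
    act <- sel[state$refr_steps[sel] == 0L]
    ref <- sel[state$refr_steps[sel] > 0L]
    if (length(act)) {
      V <- state$V[act]
      I <- sum_gv[act] - sum_g[act] * V
      Vn <- V + dt / p$tau_m * ((p$V_0 - V) + I / p$g_0)
      if (any(!is.finite(Vn)))
        stop("membrane potential diverged (dt too large?) at t = ", state$t)
      state$V[act] <- Vn
    }
    if (length(ref)) {
      state$V[ref] <- p$V_H
      state$refr_steps[ref] <- state$refr_steps[ref] - 1L
    }
  }
  state$step <- state$step + 1L
  state$t <- state$step * dt
  state
}

# grouped sum of x by integer index into 1..n
tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Decay conductances and deliver arrivals
#'
#' Every per-synapse conductance decays by the exact exponential factor
#' `exp(-dt/tau_g)` of its class; each synapse listed in `arrivals` then
#' receives an instantaneous jump of `g_scale * weight` nS. Called with
#' `dt = 0` it performs pure deliveries; with empty `arrivals`, pure decay.
#'
#' @param state a `sim_state`.
#' @param network a `spiking_network`.
#' @param arrivals integer synapse indices due in the current step.
#' @param dt elapsed time to decay over (ms, `>= 0`).
#' @return Updated `sim_state`.
#' @export
update_conductances <- function(state, network, arrivals, dt) {
  stopifnot(dt >= 0)
  if (length(arrivals)) {
    if (any(arrivals < 1 | arrivals > nrow(network$syn)))
      stop("arrival references an unknown synapse")
  }
  if (dt > 0) {
    tau <- vapply(network$syn_classes, `[[`, numeric(1), "tau_g")
    state$g <- state$g * exp(-dt / tau)[network$syn$class_id]
  }
  if (length(arrivals)) {
    gs <- vapply(network$syn_classes, `[[`, numeric(1), "g_scale")
    jump <- gs[network$syn$class_id[arrivals]] * network$syn$weight[arrivals]
    state$g[arrivals] <- state$g[arrivals] + jump
  }
  state
}

#' Threshold detection and after-spike reset
#'
#' Every non-refractory neuron at or above its class threshold emits one
#' spike stamped with the current clock, is reset to `V_H`, and starts an
#' absolute refractory countdown of `tau_R`.
#'
#' @param state a `sim_state`.
#' @param network a `spiking_network`.
#' @param dt step size (ms), used to convert `tau_R` to steps.
#' @return `list(state = , events = data.frame(neuron, time, step))`.
#' @export
detect_spikes_and_reset <- function(state, network, dt) {
  events <- list()
  for (cls in seq_along(network$neuron_params)) {
    p <- network$neuron_params[[cls]]
    sel <- which(network$nclass == cls & state$refr_steps == 0L &
                   !is.na(state$V) & state$V >= p$theta)
    if (length(sel)) {
      state$V[sel] <- p$V_H
      state$refr_steps[sel] <- as.integer(round(p$tau_R / dt))
      events[[length(events) + 1L]] <-
        data.frame(neuron = sel, time = state$t, step = state$step - 1L)
    }
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(neuron = integer(), time = numeric(), step = integer())
  list(state = state, events = ev)
}

#' Enqueue delayed deliveries for emitted spikes
#'
#' For every event and every efferent synapse of the emitting neuron, one
#' pending delivery is enqueued at `emission step + max(1, round(delay/dt))`
#' steps; the queue is kept ordered by arrival step.
#'
#' @param events data.frame with columns `neuron` and `step` (emission
#'   step index), as produced by [detect_spikes_and_reset()] (or input
#'   emissions).
#' @param network a `spiking_network`.
#' @param line delay line: data.frame `(syn_id, arrival_step)`.
#' @param dt step size (ms).
#' @return Updated delay line, ordered by `arrival_step`.
#' @export
schedule_deliveries <- function(events, network, line, dt) {
  if (nrow(events) == 0) return(line)
  syn <- network$syn
  for (r in seq_len(nrow(events))) {
    sid <- which(syn$pre == events$neuron[r])
    if (length(sid)) {
      offs <- pmax(1L, as.integer(round(syn$delay_ms[sid] / dt)))
      line <- rbind(line, data.frame(syn_id = sid,
                                     arrival_step = events$step[r] + offs))
    }
  }
  line[order(line$arrival_step, line$syn_id), , drop = FALSE]
}

#' Run one trial with the pure-R reference stepper
#'
#' Composes [update_conductances()], [integrate_step()],
#' [detect_spikes_and_reset()] and [schedule_deliveries()] (and, with
#' plasticity on, the trace STDP operations) into a full trial. This
#' stepper keeps per-synapse conductances exactly as specified and exists
#' as the readable reference implementation; [run_trial()] with the
#' compiled engine is algebraically identical and far faster.
#'
#' @inheritParams run_trial
#' @return Same contract as [run_trial()].
#' @export
run_trial_r <- function(network, input_spikes, duration, dt,
                        plasticity = plasticity_params(),
                        plasticity_on = FALSE, traces = NULL) {
  nsteps <- as.integer(floor(duration / dt + 1e-9))
  state <- new_sim_state(network)
  n <- length(network$is_input)
  traces <- traces %||% list(C = numeric(nrow(network$syn)), D = numeric(n))
  line <- data.frame(syn_id = integer(), arrival_step = integer())
  in_step <- as.integer(floor(input_spikes$time / dt + 1e-9))
  spikes <- list()
  for (k in seq_len(nsteps) - 1L) {
    # input emissions due this step
    due_in <- which(in_step == k)
    if (length(due_in)) {
      ev_in <- data.frame(neuron = input_spikes$neuron[due_in],
                          time = k * dt, step = k)
      line <- schedule_deliveries(ev_in, network, line, dt)
    }
    # arrivals
    due <- line$arrival_step == k
    arrivals <- line$syn_id[due]
    line <- line[!due, , drop = FALSE]
    state <- update_conductances(state, network, arrivals, dt = 0)
    if (plasticity_on && length(arrivals)) {
      pa <- arrivals[network$syn$plastic[arrivals]]
      if (length(pa)) {
        upd <- on_presynaptic_arrival(pa, traces, network$syn$weight,
                                      plasticity, network$syn$post)
        traces <- upd$traces; network$syn$weight <- upd$weights
      }
    }
    # membrane step, threshold, reset
    state <- integrate_step(state, network, dt)
    det <- detect_spikes_and_reset(state, network, dt)
    state <- det$state
    if (nrow(det$events)) {
      if (plasticity_on) {
        upd <- on_postsynaptic_spike(det$events$neuron, traces,
                                     network$syn$weight, network, plasticity)
        traces <- upd$traces; network$syn$weight <- upd$weights
      }
      line <- schedule_deliveries(det$events, network, line, dt)
      spikes[[length(spikes) + 1L]] <- det$events[c("neuron", "time")]
    }
    # decay phase
    state <- update_conductances(state, network, integer(0), dt)
    if (plasticity_on) traces <- decay_traces(traces, dt, plasticity)
  }
  sp <- if (length(spikes)) do.call(rbind, spikes)
        else data.frame(neuron = integer(), time = numeric())
  list(spikes = sp, weights = network$syn$weight, traces = traces,
       V = state$V)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one trial of the network
#'
#' Simulates the network for `duration` ms at step `dt` under externally
#' supplied input-layer spike trains, returning all spikes of the
#' simulated (non-input) neurons. With `plasticity_on = TRUE`, plastic
#' weights and STDP traces are updated event-wise and the final weights
#' are returned; with it off, weights are untouched. The computation is
#' fully deterministic: identical network, inputs and arguments give a
#' bit-identical spike record.
#'
#' @param network a `spiking_network`.
#' @param input_spikes data.frame `(neuron, time)` of input-layer
#'   emissions, times in `[0, duration]` ms.
#' @param duration trial length (ms); rounded down to a multiple of `dt`
#'   with a warning if not already one.
#' @param dt Euler step (ms); the reference value is 0.02.
#' @param plasticity a [plasticity_params()] object.
#' @param plasticity_on logical; apply STDP during the trial?
#' @param traces optional starting trace state
#'   `list(C = per-synapse, D = per-neuron)`; zeros when `NULL`.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference stepper).
#' @return `list(spikes = data.frame(neuron, time), weights, traces, V)`.
#' @export
run_trial <- function(network, input_spikes, duration, dt = 0.02,
                      plasticity = plasticity_params(),
                      plasticity_on = FALSE, traces = NULL,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(network, "spiking_network"), dt > 0, duration > 0)
  if (nrow(input_spikes) > 0) {
    if (!all(network$is_input[input_spikes$neuron]))
      stop("input spikes must reference input-layer units")
    if (any(input_spikes$time < 0 | input_spikes$time > duration))
      stop("input spike times must lie within [0, duration]")
  }
  nsteps <- floor(duration / dt + 1e-9)
  if (abs(nsteps * dt - duration) > 1e-9 * max(1, duration))
    warning("duration is not a multiple of dt; rounded down to ",
            nsteps * dt, " ms")
  if (engine == "r")
    return(run_trial_r(network, input_spikes, duration, dt,
                       plasticity, plasticity_on, traces))
  np <- t(vapply(network$neuron_params, function(p)
    c(p$C_m, p$g_0, p$V_0, p$theta, p$V_H, p$tau_R), numeric(6)))
  sp <- t(vapply(network$syn_classes, function(p)
    c(p$tau_g, p$V_rev, p$g_scale), numeric(3)))
  res <- run_trial_engine(
    network$syn$pre, network$syn$post, network$syn$class_id,
    network$syn$plastic, network$syn$weight, network$syn$delay_ms,
    network$nclass, np, sp,
    as.integer(input_spikes$neuron), as.numeric(input_spikes$time),
    duration, dt, isTRUE(plasticity_on),
    plasticity$alpha_c, plasticity$alpha_d,
    plasticity$tau_c, plasticity$tau_d, plasticity$rho,
    traces$C %||% numeric(0), traces$D %||% numeric(0))
  list(spikes = data.frame(neuron = res$spike_neuron, time = res$spike_time),
       weights = res$weights,
       traces = list(C = res$trace_c, D = res$trace_d),
       V = res$V)
}
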