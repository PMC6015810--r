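#' Build a response table from recorded spike rates
#'
#' @param cell,stimulus,transform,rate parallel vectors: one row per
#'   (cell, stimulus, transform) with the measured firing rate (Hz).
#' @return A `response_table` data.frame.
#' @export
response_table <- function(cell, stimulus, transform, rate) {
  out <- data.frame(cell = cell, stimulus = stimulus,
                    transform = transform, rate = as.numeric(rate))
  class(out) <- c("response_table", "data.frame")
  out
}

#' Discretize firing rates into response bins
#'
#' Per cell, equal-width bins spanning \[0, max observed rate\] for that
#' cell. Bins are right-closed, `(low, high]`, with the lowest bin closed
#' at zero so a zero rate always maps to bin 0. A cell whose responses
#' are all equal lands in a single bin. Re-binning already-binned labels
#' with the same `n_bins` is the identity.
#'
#' @param table a `response_table`.
#' @param n_bins number of bins (default 10).
#' @return The table with a `bin` column (labels `0 .. n_bins-1`).
#' @export
bin_responses <- function(table, n_bins = 10) {
  stopifnot(n_bins >= 2)
  bin1 <- function(r) {
    m <- max(r)
    if (m <= 0) return(rep(0L, length(r)))
    b <- as.integer(ceiling(r / (m / n_bins)) - 1L)
    pmin(pmax(b, 0L), n_bins - 1L)
  }
  table$bin <- stats::ave(table$rate, table$cell, FUN = bin1)
  table
}

# stimulus-specific information (bits) from a counts matrix
# rows = stimuli, cols = response bins; entries = transform counts
info_bits_from_counts <- function(counts) {
  n_s <- rowSums(counts)
  p_r_s <- counts / n_s
  p_s <- n_s / sum(n_s)                # transform-weighted stimulus prior
  p_r <- colSums(p_r_s * p_s)          # marginal response distribution
  apply(p_r_s, 1, function(pr) {
    nz <- pr > 0
    sum(pr[nz] * log2(pr[nz] / p_r[nz]))
  })
}

#' Stimulus-specific information per cell
#'
#' For each cell and stimulus `s`, computes
#' `I(s, R) = sum_r P(r|s) log2( P(r|s) / P(r) )` over the discretized
#' responses `r`, with `P(r)` the transform-weighted marginal. The ceiling
#' is `log2(n_stimuli)` bits, attained by a cell responding in a unique
#' bin to every transform of exactly one stimulus.
#'
#' @param table a `response_table`; binned with [bin_responses()] first
#'   (auto-binned with 10 bins when the `bin` column is missing).
#' @return A list with `per_stimulus` (cell, stimulus, info_bits),
#'   `per_cell` (cell, max_info_bits, best_stimulus, rank; rank 1 =
#'   most informative) and `ceiling_bits`.
#' @export
stimulus_specific_information <- function(table) {
  if (nrow(table) == 0) stop("empty response table")
  if (is.null(table$bin)) table <- bin_responses(table)
  stims <- sort(unique(table$stimulus))
  if (length(stims) < 2) stop("need at least two stimuli")
  bins <- sort(unique(table$bin))
  per_stim <- do.call(rbind, lapply(split(table, table$cell), function(tb) {
    counts <- table(factor(tb$stimulus, levels = stims),
                    factor(tb$bin, levels = bins))
    data.frame(cell = tb$cell[1], stimulus = stims,
               info_bits = info_bits_from_counts(unclass(counts)))
  }))
  rownames(per_stim) <- NULL
  per_cell <- do.call(rbind, lapply(split(per_stim, per_stim$cell),
    function(d) {
      k <- which.max(d$info_bits)
      data.frame(cell = d$cell[1], max_info_bits = d$info_bits[k],
                 best_stimulus = d$stimulus[k])
    }))
  per_cell <- per_cell[order(-per_cell$max_info_bits), ]
  per_cell$rank <- seq_len(nrow(per_cell))
  rownames(per_cell) <- NULL
  list(per_stimulus = per_stim, per_cell = per_cell,
       ceiling_bits = max_information(length(stims)))
}

#' Spike-pair occurrence table (two-spike polychronous groups)
#'
#' For every ordered neuron pair (i, j) and inter-spike interval bin `d`,
#' marks the pair "present" in a transform when neuron i emits a spike
#' within interval bin `d` after any spike of neuron j; the per-stimulus
#' probability is the fraction of that stimulus' transforms in which the
#' pair occurred. The interval window `[0, window]` ms is divided into
#' `bins` equal bins (reference: 10 bins of 1 ms); spike times are
#' discretized at the bin width, so bin `d` holds lags of `d` time bins.
#' Self-pairs (i == j) are excluded.
#'
#' @param records data.frame `(stimulus, transform, neuron, time)` of
#'   onset-aligned spikes (one presentation per (stimulus, transform)).
#' @param neurons neuron ids to consider (default: all in `records`).
#' @param window lag window (ms).
#' @param bins number of interval bins.
#' @param count_weighted if `TRUE`, presence is replaced by occurrence
#'   counts (spike-count weighting); default is binary presence.
#' @return A `pair_png_table` data.frame
#'   `(j, i, d, stimulus, prob)` covering every stimulus for every pair
#'   observed at least once, with attribute `n_transforms`.
#' @export
build_pair_png_table <- function(records, neurons = NULL, window = 10,
                                 bins = 10, count_weighted = FALSE) {
  if (is.null(neurons)) neurons <- sort(unique(records$neuron))
  if (nrow(records) == 0) {
    out <- data.frame(j = integer(), i = integer(), d = integer(),
                      stimulus = character(), prob = numeric())
    attr(out, "n_transforms") <- integer(0)
    class(out) <- c("pair_png_table", "data.frame")
    return(out)
  }
  binw <- window / bins
  stims <- sort(unique(records$stimulus))
  n_tr <- integer(length(stims)); names(n_tr) <- stims
  nn <- length(neurons)
  t_max <- max(records$time)
  n_tbin <- max(as.integer(ceiling(t_max / binw)) + 1L, bins + 1L)
  nmap <- stats::setNames(seq_along(neurons), neurons)
  # pair-bin code: ((i_idx - 1) * nn + (j_idx - 1)) * bins + d
  codes_by_stim <- vector("list", length(stims))
  vals_by_stim <- vector("list", length(stims))
  for (s_idx in seq_along(stims)) {
    rs <- records[records$stimulus == stims[s_idx], ]
    trs <- unique(rs$transform)
    n_tr[s_idx] <- length(trs)
    acc_codes <- list(); acc_vals <- list()
    for (tr in trs) {
      rt <- rs[rs$transform == tr & rs$neuron %in% neurons, ]
      S <- matrix(0L, nn, n_tbin)
      if (nrow(rt)) {
        tb <- pmin(as.integer(floor(rt$time / binw)) + 1L, n_tbin)
        S[cbind(nmap[as.character(rt$neuron)], tb)] <- 1L
      }
      for (d in seq_len(bins) - 1L) {
        # present(i, j): i spikes d lag-bins after j
        A <- if (d == 0) S
             else cbind(S[, (d + 1L):n_tbin, drop = FALSE],
                        matrix(0L, nn, d))
        M <- A %*% t(S)                 # M[i, j] = co-occurrence count
        diag(M) <- 0
        hit <- which(M > 0)
        if (length(hit)) {
          i_idx <- (hit - 1L) %% nn     # 0-based row (cell i)
          j_idx <- (hit - 1L) %/% nn    # 0-based col (cell j)
          acc_codes[[length(acc_codes) + 1L]] <-
            (i_idx * nn + j_idx) * bins + d
          if (count_weighted)
            acc_vals[[length(acc_vals) + 1L]] <- M[hit]
        }
      }
    }
    codes_by_stim[s_idx] <- list(unlist(acc_codes))
    if (count_weighted) vals_by_stim[s_idx] <- list(unlist(acc_vals))
  }
  all_codes <- sort(unique(unlist(codes_by_stim)))
  if (length(all_codes) == 0) {
    out <- data.frame(j = integer(), i = integer(), d = integer(),
                      stimulus = character(), prob = numeric())
  } else {
    per_stim <- lapply(seq_along(stims), function(s_idx) {
      cd <- codes_by_stim[[s_idx]]
      pos <- match(cd, all_codes)
      if (count_weighted) {
        v <- numeric(length(all_codes))
        tmp <- rowsum(vals_by_stim[[s_idx]], pos)
        v[as.integer(rownames(tmp))] <- tmp[, 1]
        v
      } else tabulate(pos, nbins = length(all_codes))
    })
    d <- all_codes %% bins
    pair <- all_codes %/% bins
    i_idx <- pair %/% nn + 1L
    j_idx <- pair %% nn + 1L
    out <- data.frame(
      j = rep(neurons[j_idx], length(stims)),
      i = rep(neurons[i_idx], length(stims)),
      d = rep(as.integer(d), length(stims)),
      stimulus = rep(stims, each = length(all_codes)),
      prob = unlist(per_stim) / rep(n_tr, each = length(all_codes)))
  }
  attr(out, "n_transforms") <- n_tr
  class(out) <- c("pair_png_table", "data.frame")
  out
}

#' Stimulus information carried by spike-pair occurrences
#'
#' Treats each (pair, interval-bin) presence/absence pattern as the
#' response variable and applies the single-cell information formula:
#' `I(s) = sum_{r in {present, absent}} P(r|s) log2(P(r|s)/P(r))`. A pair
#' present in all transforms of one of `n` stimuli and absent otherwise
#' attains the `log2(n)` ceiling.
#'
#' @param table a `pair_png_table` from [build_pair_png_table()].
#' @return data.frame `(j, i, d, max_info_bits, best_stimulus)` sorted by
#'   decreasing information.
#' @export
pair_png_information <- function(table) {
  n_tr <- attr(table, "n_transforms")
  if (nrow(table) == 0)
    return(data.frame(j = integer(), i = integer(), d = integer(),
                      max_info_bits = numeric(), best_stimulus = character()))
  stims <- names(n_tr)
  # rows come stimulus-blocked from the builder; reshape to codes x stimuli
  ord <- order(table$stimulus, table$j, table$i, table$d)
  tb <- table[ord, ]
  n_codes <- nrow(tb) / length(stims)
  p1 <- matrix(tb$prob, n_codes, length(stims))
  ids <- tb[seq_len(n_codes), c("j", "i", "d")]
  p_s <- n_tr / sum(n_tr)
  m1 <- as.numeric(p1 %*% p_s)         # marginal presence probability
  m0 <- 1 - m1
  xlx <- function(p, m) ifelse(p > 0, p * log2(p / pmax(m, .Machine$double.xmin)), 0)
  info <- xlx(p1, m1) + xlx(1 - p1, m0)
  best <- max.col(info, ties.method = "first")
  out <- data.frame(j = ids$j, i = ids$i, d = ids$d,
                    max_info_bits = info[cbind(seq_len(n_codes), best)],
                    best_stimulus = stims[best])
  out <- out[order(-out$max_info_bits), ]
  rownames(out) <- NULL
  out
}

#' First-spike timing statistics across trials
#'
#' Restricted to neurons that responded (emitted at least one spike) in
#' every trial; for each such neuron, the mean and sample standard
#' deviation (n-1 denominator) of its first-spike time across trials.
#'
#' @param records data.frame `(trial, neuron, time)` of onset-relative
#'   spikes over at least two trials.
#' @return data.frame `(neuron, n_trials, mean_ms, sd_ms)`.
#' @export
first_spike_statistics <- function(records) {
  trials <- unique(records$trial)
  if (length(trials) < 2) stop("need at least two trials")
  first <- stats::aggregate(time ~ trial + neuron, records, min)
  n_per <- table(first$neuron)
  keep <- as.integer(names(n_per)[n_per == length(trials)])
  first <- first[first$neuron %in% keep, ]
  if (nrow(first) == 0) {
    message("no neuron responded in every trial")
    return(data.frame(neuron = integer(), n_trials = integer(),
                      mean_ms = numeric(), sd_ms = numeric()))
  }
  agg <- do.call(rbind, lapply(split(first$time, first$neuron), function(x)
    data.frame(n_trials = length(x), mean_ms = mean(x),
               sd_ms = stats::sd(x))))
  data.frame(neuron = as.integer(rownames(agg)), agg, row.names = NULL)
}

#' Detect delay-consistent three-neuron binding circuits
#'
#' Finds every ordered triple (low-level neuron 1, high-level neuron 2,
#' binder 3) such that synapses 1->2, 1->3 and 2->3 all carry weight at
#' least `weight_threshold` and the axonal delays satisfy the binding
#' relation `delta(3,1) = delta(2,1) + delta(3,2)` within
#' `delay_tolerance` ms: the direct spike from 1 and the indirect spike
#' via 2 then arrive at the binder together, so the binder can act as a
#' coincidence detector for "1 drove 2".
#'
#' @param network a trained `spiking_network`.
#' @param weight_threshold minimum weight for a synapse to count as
#'   strengthened (default half the maximum weight present).
#' @param delay_tolerance residual tolerance (ms; default 1, one interval
#'   bin).
#' @return data.frame `(low, high, binder, d21, d31, d32, residual_ms,
#'   layer_low, layer_high, layer_binder)`.
#' @export
find_binding_circuits <- function(network,
                                  weight_threshold = 0.5 * max(network$syn$weight),
                                  delay_tolerance = 1) {
  syn <- network$syn
  strong <- syn[syn$weight >= weight_threshold & !network$is_input[syn$pre],
                c("pre", "post", "delay_ms")]
  if (nrow(strong) == 0)
    return(empty_binding_records())
  e12 <- stats::setNames(strong, c("low", "high", "d21"))
  e23 <- stats::setNames(strong, c("high", "binder", "d32"))
  e13 <- stats::setNames(strong, c("low", "binder", "d31"))
  tri <- merge(e12, e23, by = "high")
  tri <- tri[tri$low != tri$binder, , drop = FALSE]
  tri <- merge(tri, e13, by = c("low", "binder"))
  if (nrow(tri) == 0) return(empty_binding_records())
  tri$residual_ms <- abs(tri$d31 - (tri$d21 + tri$d32))
  tri <- tri[tri$residual_ms <= delay_tolerance, , drop = FALSE]
  out <- data.frame(low = tri$low, high = tri$high, binder = tri$binder,
                    d21 = tri$d21, d31 = tri$d31, d32 = tri$d32,
                    residual_ms = tri$residual_ms,
                    layer_low = network$layer[tri$low],
                    layer_high = network$layer[tri$high],
                    layer_binder = network$layer[tri$binder])
  out <- out[order(out$residual_ms), ]
  rownames(out) <- NULL
  out
}

empty_binding_records <- function() {
  data.frame(low = integer(), high = integer(), binder = integer(),
             d21 = numeric(), d31 = numeric(), d32 = numeric(),
             residual_ms = numeric(), layer_low = integer(),
             layer_high = integer(), layer_binder = integer())
}

#' Construct an isolated three-neuron binding probe network
#'
#' Two input units drive the low-level neuron (1) and, optionally for
#' non-causal probes, the high-level neuron (2) directly. The 1->2
#' synapse is strong enough to fire neuron 2 on its own; the two
#' convergent synapses onto the binder (1->3 and 2->3) use a fast
#' synaptic time constant (default 1 ms) and a conductance scale such
#' that a single afferent volley stays subthreshold while two volleys
#' arriving within about +/-1.5 ms fire the binder. With the slow 20 ms
#' membrane, a 2 ms synaptic constant leaves no usable coincidence
#' margin (temporal summation over the membrane dominates), so the probe
#' defaults to 1 ms.
#'
#' @param d21,d31,d32 the circuit's axonal delays (ms).
#' @param drive12 logical; include the 1->2 synapse (disable to probe
#'   independent, non-causal co-activation).
#' @param binder_scale conductance scale (nS) of each binder afferent.
#' @param tau_g_binder synaptic time constant (ms) of the binder
#'   afferents (fast, to make the binder a coincidence detector).
#' @return A `spiking_network` with input units 1 (-> neuron 1) and
#'   2 (-> neuron 2); neurons 3, 4, 5 are the circuit's 1, 2, 3.
#' @export
make_binding_probe_network <- function(d21, d31, d32, drive12 = TRUE,
                                       binder_scale = 100, tau_g_binder = 1) {
  np <- default_neuron_params()$excitatory
  # drive synapses are strong and brief (tau_g = 0.3 ms) so an externally
  # driven neuron emits exactly one spike, ~0.3 ms after the volley
  classes <- list(
    drive = synapse_class_params("drive", 0.3, 0, 1000, FALSE),
    strong = synapse_class_params("strong", 0.3, 0, 1000, FALSE),
    binder = synapse_class_params("binder", tau_g_binder, 0,
                                  binder_scale, FALSE))
  n1 <- 3L; n2 <- 4L; n3 <- 5L
  syn <- data.frame(
    pre = c(1L, 2L, n1, n1, n2),
    post = c(n1, n2, n2, n3, n3),
    weight = c(1, 1, if (drive12) 1 else 0, 1, 1),
    delay_ms = c(0.1, 0.1, d21, d31, d32),
    class_id = c(1L, 1L, 2L, 3L, 3L),
    plastic = FALSE)
  class(syn) <- c("connection_group", "data.frame")
  new_spiking_network(
    is_input = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    layer = c(0L, 0L, 1L, 2L, 2L),
    nclass = c(0L, 0L, 1L, 1L, 1L),
    pos = NULL, neuron_params = list(np),
    syn_classes = classes, syn = syn,
    meta = list(kind = "binding_probe", d21 = d21, d31 = d31, d32 = d32))
}

#' Verify the binder's fire-iff-causally-driven contract
#'
#' Probes a delay-consistent triple in an isolated runnable circuit:
#' (a) when neuron 1's spike causally drives neuron 2, the binder must
#' fire (its two afferent volleys coincide by the delay relation);
#' (b) when neurons 1 and 2 are driven independently at non-causal
#' offsets (the 1->2 synapse disabled), and when neuron 2 fires alone,
#' the binder must stay silent.
#'
#' @param circuit one row of [find_binding_circuits()] output, or any
#'   list with `d21`, `d31`, `d32` (ms).
#' @param noncausal_offsets_ms offsets (ms) added to the causal arrival
#'   alignment when driving neuron 2 independently; all must leave the
#'   binder silent.
#' @param dt integration step (ms).
#' @return `TRUE` iff both conditions hold; attributes `causal_fired`
#'   and `noncausal_fired` give the per-probe outcomes.
#' @export
verify_binding_behavior <- function(circuit,
                                    noncausal_offsets_ms = c(-8, -5, 5, 8),
                                    dt = 0.02) {
  d21 <- circuit$d21; d31 <- circuit$d31; d32 <- circuit$d32
  dur <- 60
  probe <- function(net, in_spikes) {
    res <- run_trial(net, in_spikes, duration = dur, dt = dt)
    any(res$spikes$neuron == 5L)
  }
  # (a) causal drive: input 1 only, 1->2 enabled
  net_c <- make_binding_probe_network(d21, d31, d32, drive12 = TRUE)
  causal <- probe(net_c, data.frame(neuron = 1L, time = 5))
  # (b) neuron 2 alone
  net_n <- make_binding_probe_network(d21, d31, d32, drive12 = FALSE)
  alone <- probe(net_n, data.frame(neuron = 2L, time = 5))
  # (b) independent co-activation at non-causal offsets
  # measured spike latencies under the probe drive
  lat1 <- neuron_latency(net_n, 1L, 3L, dt, dur)
  lat2 <- neuron_latency(net_n, 2L, 4L, dt, dur)
  nonc <- vapply(noncausal_offsets_ms, function(off) {
    # align so that, at off = 0, the two volleys would coincide at the binder
    t2 <- 5 + lat1 + d31 - d32 - lat2 + off
    if (t2 < 0 || t2 > dur) return(FALSE)
    probe(net_n, data.frame(neuron = c(1L, 2L), time = c(5, t2)))
  }, logical(1))
  ok <- causal && !alone && !any(nonc)
  structure(ok, causal_fired = causal,
            noncausal_fired = any(nonc) || alone)
}

# latency from an input spike to the driven neuron's spike
neuron_latency <- function(net, input_id, neuron_id, dt, dur) {
  res <- run_trial(net, data.frame(neuron = input_id, time = 5),
                   duration = dur, dt = dt)
  ft <- res$spikes$time[res$spikes$neuron == neuron_id]
  if (!length(ft)) stop("probe drive failed to fire neuron ", neuron_id)
  min(ft) - 5
}
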