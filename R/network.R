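#' Connection group
#'
#' Parallel-array representation of a set of synapses: presynaptic index,
#' postsynaptic index, dimensionless efficacy in \[0, 1\], axonal
#' conduction delay (ms) and synapse class.
#'
#' @param pre,post integer neuron indices.
#' @param weight efficacies in \[0, 1\].
#' @param delay_ms conduction delays (ms), non-negative.
#' @param class_id integer index into the network's synapse class list.
#' @param plastic logical, per synapse.
#' @return A `data.frame` with class `connection_group`.
#' @export
connection_group <- function(pre, post, weight, delay_ms, class_id, plastic) {
  n <- length(pre)
  stopifnot(length(post) == n)
  weight <- rep_len(as.numeric(weight), n)
  delay_ms <- rep_len(as.numeric(delay_ms), n)
  if (any(weight < 0 | weight > 1)) stop("weights must lie in [0, 1]")
  if (any(delay_ms < 0)) stop("delays must be non-negative")
  out <- data.frame(pre = as.integer(pre), post = as.integer(post),
                    weight = weight,
                    delay_ms = delay_ms,
                    class_id = as.integer(rep_len(class_id, n)),
                    plastic = rep_len(as.logical(plastic), n))
  class(out) <- c("connection_group", "data.frame")
  out
}

#' Sample axonal conduction delays
#'
#' Draws `n` i.i.d. delays uniformly from `range` (ms). With
#' `range[1] == range[2]` all delays are identical (the uniform-delay
#' synchrony control).
#'
#' @param n number of delays.
#' @param range length-2 numeric, `low <= high`, both non-negative (ms).
#' @param seed optional integer; when given, sampling is done in a local
#'   RNG scope that does not disturb the caller's RNG stream.
#' @return numeric vector of delays (ms).
#' @export
sample_delays <- function(n, range = c(0.1, 10), seed = NULL) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  if (any(range < 0)) stop("delay bounds must be non-negative")
  draw <- function() {
    if (range[1] == range[2]) rep(range[1], n) else stats::runif(n, range[1], range[2])
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

new_spiking_network <- function(is_input, layer, nclass, pos,
                                neuron_params, syn_classes, syn, meta = list()) {
  structure(list(is_input = is_input, layer = layer, nclass = nclass,
                 pos = pos, neuron_params = neuron_params,
                 syn_classes = syn_classes, syn = syn, meta = meta),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat("<spiking_network>\n")
  cat("  neurons:", length(x$is_input),
      sprintf("(%d input, %d simulated)", sum(x$is_input), sum(!x$is_input)), "\n")
  cat("  layers :", paste(sort(unique(x$layer)), collapse = " "), "\n")
  cat("  synapses:", nrow(x$syn), "in",
      length(x$syn_classes), "classes\n")
  invisible(x)
}

# Sample `count` afferents for one postsynaptic neuron from the pre-layer
# cells whose grid position lies within `radius` (Euclidean, pre-grid cells,
# no wraparound) of the mapped post position. Without replacement when the
# disc holds enough candidates, otherwise with replacement.
sample_topographic <- function(center_xy, radius, pre_lookup, pre_w, pre_h, count) {
  r <- ceiling(radius)
  xs <- max(1, floor(center_xy[1] - r)):min(pre_w, ceiling(center_xy[1] + r))
  ys <- max(1, floor(center_xy[2] - r)):min(pre_h, ceiling(center_xy[2] + r))
  grid <- expand.grid(x = xs, y = ys)
  d2 <- (grid$x - center_xy[1])^2 + (grid$y - center_xy[2])^2
  keep <- d2 <= radius^2 + 1e-9
  cells <- grid[keep, , drop = FALSE]
  cand <- unlist(pre_lookup[(cells$y - 1L) * pre_w + cells$x], use.names = FALSE)
  if (length(cand) == 0) stop("empty fan-in disc: radius too small")
  replace <- length(cand) < count
  res <- if (length(cand) == 1L) rep(cand, count)
         else sample(cand, count, replace = replace)
  attr(res, "replaced") <- replace
  res
}

# Map position index -> (x, y) on a w x h grid (column-major by row),
# 1-based cell centers.
grid_xy <- function(idx, w) cbind(x = ((idx - 1L) %% w) + 1L,
                                  y = ((idx - 1L) %/% w) + 1L)

# Proportional mapping of a position on the post grid onto pre-grid
# coordinates (continuous).
map_position <- function(xy, post_w, post_h, pre_w, pre_h) {
  c((xy[1] - 0.5) / post_w * pre_w + 0.5,
    (xy[2] - 0.5) / post_h * pre_h + 0.5)
}

# Build one topographic projection block: every post neuron in `post_ids`
# (with grid positions post_xy on a post_w x post_h grid) receives `count`
# afferents drawn from `pre_ids` arranged on a pre_w x pre_h grid (several
# pre neurons may share a grid cell, e.g. orientation/phase channels).
topographic_block <- function(pre_ids, pre_cell, pre_w, pre_h,
                              post_ids, post_w, post_h,
                              count, radius, delay_range, class_id, plastic,
                              w_max = 1, exclude_self = FALSE) {
  if (count == 0 || length(post_ids) == 0) return(NULL)
  pre_lookup <- split(pre_ids, factor(pre_cell, levels = seq_len(pre_w * pre_h)))
  pre <- vector("list", length(post_ids))
  n_replaced <- 0L
  for (k in seq_along(post_ids)) {
    xy <- grid_xy(k, post_w)[1, ]
    ctr <- map_position(xy, post_w, post_h, pre_w, pre_h)
    aff <- sample_topographic(ctr, radius, pre_lookup, pre_w, pre_h,
                              if (exclude_self) count + 1L else count)
    if (isTRUE(attr(aff, "replaced"))) n_replaced <- n_replaced + 1L
    if (exclude_self) {
      aff <- aff[aff != post_ids[k]]
      aff <- aff[seq_len(min(count, length(aff)))]
    }
    pre[[k]] <- as.integer(aff)
  }
  if (n_replaced > 0)
    message(sprintf(
      "fan-in disc smaller than requested count for %d/%d neurons; sampled with replacement",
      n_replaced, length(post_ids)))
  npre <- lengths(pre)
  pre <- unlist(pre, use.names = FALSE)
  n <- length(pre)
  connection_group(pre, rep(post_ids, npre),
                   if (plastic) stats::runif(n, 0, w_max) else rep(1, n),
                   sample_delays(n, delay_range), class_id, plastic)
}

#' Build the two-layer feedforward polychronization model
#'
#' A one-dimensional input layer of Poisson units projects to a first
#' layer of excitatory LIF neurons (connection probability 0.2, delays
#' uniform on `delay_in`), which projects to a second LIF layer
#' (probability 0.02, delays uniform on `delay_12`). All connections are
#' plastic feedforward excitatory synapses; there are no interneurons.
#'
#' @param seed integer RNG seed for wiring.
#' @param n_per_layer neurons per layer (1000 in the reference
#'   configuration; reduce for quick runs).
#' @param p_in,p_12 connection probabilities input->layer 1 and
#'   layer 1 -> layer 2.
#' @param delay_in,delay_12 delay ranges (ms). `delay_12 = c(1, 1)` gives
#'   the uniform-delay synchrony control.
#' @param w_init_max upper bound of the uniform initial-weight
#'   distribution. The default 0.05 places the expected
#'   threshold-crossing time of a layer-1 neuron a few tens of ms into
#'   the presentation (see the package vignette), so that before training
#'   only part of each layer responds on every trial.
#' @return A `spiking_network`.
#' @export
build_two_layer <- function(seed, n_per_layer = 1000,
                            p_in = 0.2, p_12 = 0.02,
                            delay_in = c(1, 10), delay_12 = c(1, 30),
                            w_init_max = 0.05) {
  set.seed(seed)
  n <- n_per_layer
  ids_in <- seq_len(n); ids_l1 <- n + seq_len(n); ids_l2 <- 2L * n + seq_len(n)
  n_tot <- 3L * n
  # Bernoulli wiring: for each post neuron, each candidate pre is connected
  # independently with the stated probability.
  wire <- function(pre_ids, post_ids, p) {
    m <- matrix(stats::runif(length(pre_ids) * length(post_ids)) < p,
                nrow = length(pre_ids))
    idx <- which(m, arr.ind = TRUE)
    list(pre = pre_ids[idx[, 1]], post = post_ids[idx[, 2]])
  }
  w1 <- wire(ids_in, ids_l1, p_in)
  w2 <- wire(ids_l1, ids_l2, p_12)
  syn_classes <- list(EfE = synapse_class_params("EfE", 150, 0, 1.6, TRUE))
  g1 <- connection_group(w1$pre, w1$post,
                         stats::runif(length(w1$pre), 0, w_init_max),
                         sample_delays(length(w1$pre), delay_in), 1L, TRUE)
  g2 <- connection_group(w2$pre, w2$post,
                         stats::runif(length(w2$pre), 0, w_init_max),
                         sample_delays(length(w2$pre), delay_12), 1L, TRUE)
  syn <- rbind(g1, g2)
  class(syn) <- c("connection_group", "data.frame")
  new_spiking_network(
    is_input = c(rep(TRUE, n), rep(FALSE, 2L * n)),
    layer = rep(0:2, each = n),
    nclass = c(rep(0L, n), rep(1L, 2L * n)),
    pos = NULL,
    neuron_params = list(default_neuron_params()$excitatory),
    syn_classes = syn_classes, syn = syn,
    meta = list(kind = "two_layer", seed = seed, n_per_layer = n))
}

#' Build the four-layer ventral-stream architecture
#'
#' Four hierarchical layers, each holding a square grid of excitatory and
#' a half-resolution grid of inhibitory LIF neurons, driven by a retinal
#' input layer of Gabor-filter units (one unit per retinal location,
#' orientation and phase). Excitatory-excitatory feedforward (EfE),
#' feedback (EbE) and lateral (ElE) projections are plastic; the
#' excitatory-inhibitory loop (ElI, IlE) is fixed. Connectivity is
#' topographic: each postsynaptic neuron samples its afferents from a
#' Euclidean disc of the stated fan-in radius around its mapped position
#' on the presynaptic grid (no wraparound; sampling falls back to
#' with-replacement when the disc is smaller than the requested count).
#'
#' At reduced scale (`grid_e < 64`) only the grids shrink; the per-neuron
#' fan-in counts and radii keep their reference values so each neuron's
#' input statistics match the full model.
#'
#' @param seed wiring seed.
#' @param grid_e excitatory grid side per layer (reference 64).
#' @param grid_i inhibitory grid side (reference 32; default `grid_e/2`).
#' @param retina retinal grid side (reference 128; default `2*grid_e`).
#' @param n_orientations,n_phases Gabor channels per retinal location.
#' @param ff_counts,ff_radii feedforward counts/radii for layers 1-4.
#' @param fb_count,lat_count feedback and lateral afferents per excitatory
#'   neuron (0 disables the pathway; 10 is the reference "on" value).
#' @param eli_count,eli_radius,ile_count,ile_radius interneuron loop.
#' @param fb_radius,lat_radius fan-in radii for EbE / ElE.
#' @param delay_range axonal delay range (ms) for all connections.
#' @param contacts_per_pair synaptic contacts per connected pre/post pair
#'   (M); with M > 1 every drawn pair is represented by M synapses with
#'   independently sampled delays from `contact_delay_range`.
#' @param contact_delay_range delay range for multi-contact synapses (ms).
#' @param w_init_max upper bound of uniform initial plastic weights.
#' @return A `spiking_network`.
#' @export
build_four_layer <- function(seed, grid_e = 64, grid_i = grid_e / 2,
                             retina = 2 * grid_e,
                             n_orientations = 4, n_phases = 2,
                             ff_counts = c(30, 100, 100, 100),
                             ff_radii = c(1, 8, 12, 16),
                             fb_count = 10, fb_radius = 8,
                             lat_count = 10, lat_radius = 4,
                             eli_count = 30, eli_radius = 1,
                             ile_count = 30, ile_radius = 8,
                             delay_range = c(0.1, 10),
                             contacts_per_pair = 1,
                             contact_delay_range = c(0, 10),
                             w_init_max = 1) {
  set.seed(seed)
  grid_i <- as.integer(grid_i); grid_e <- as.integer(grid_e)
  n_chan <- n_orientations * n_phases
  n_in <- retina * retina * n_chan
  nE <- grid_e^2; nI <- grid_i^2
  n_tot <- n_in + 4L * (nE + nI)

  is_input <- c(rep(TRUE, n_in), rep(FALSE, 4L * (nE + nI)))
  layer <- c(rep(0L, n_in), rep(1:4, each = nE + nI))
  nclass <- c(rep(0L, n_in), rep(rep(c(1L, 2L), times = c(nE, nI)), 4))

  # ids per population
  idsE <- lapply(0:3, function(l) n_in + l * (nE + nI) + seq_len(nE))
  idsI <- lapply(0:3, function(l) n_in + l * (nE + nI) + nE + seq_len(nI))
  # retinal cell of each input unit (n_chan units per location)
  in_cell <- rep(seq_len(retina * retina), each = n_chan)

  scl <- default_synapse_classes()
  class_ids <- stats::setNames(seq_along(scl), names(scl))

  blocks <- list()
  add <- function(b) if (!is.null(b)) blocks[[length(blocks) + 1L]] <<- b

  # GfE: retina -> layer 1 excitatory
  add(topographic_block(seq_len(n_in), in_cell, retina, retina,
                        idsE[[1]], grid_e, grid_e,
                        ff_counts[1], ff_radii[1], delay_range,
                        class_ids["GfE"], TRUE, w_init_max))
  # EfE: E(l-1) -> E(l)
  for (l in 2:4)
    add(topographic_block(idsE[[l - 1]], seq_len(nE), grid_e, grid_e,
                          idsE[[l]], grid_e, grid_e,
                          ff_counts[l], ff_radii[l], delay_range,
                          class_ids["EfE"], TRUE, w_init_max))
  # EbE: E(l+1) -> E(l)
  if (fb_count > 0)
    for (l in 1:3)
      add(topographic_block(idsE[[l + 1]], seq_len(nE), grid_e, grid_e,
                            idsE[[l]], grid_e, grid_e,
                            fb_count, fb_radius, delay_range,
                            class_ids["EbE"], TRUE, w_init_max))
  # ElE: lateral E -> E within layer (self-connections excluded)
  if (lat_count > 0)
    for (l in 1:4)
      add(topographic_block(idsE[[l]], seq_len(nE), grid_e, grid_e,
                            idsE[[l]], grid_e, grid_e,
                            lat_count, lat_radius, delay_range,
                            class_ids["ElE"], TRUE, w_init_max,
                            exclude_self = TRUE))
  # ElI and IlE interneuron loop
  for (l in 1:4) {
    add(topographic_block(idsE[[l]], seq_len(nE), grid_e, grid_e,
                          idsI[[l]], grid_i, grid_i,
                          eli_count, eli_radius, delay_range,
                          class_ids["ElI"], FALSE))
    add(topographic_block(idsI[[l]], seq_len(nI), grid_i, grid_i,
                          idsE[[l]], grid_e, grid_e,
                          ile_count, ile_radius, delay_range,
                          class_ids["IlE"], FALSE))
  }
  syn <- do.call(rbind, blocks)
  class(syn) <- c("connection_group", "data.frame")

  pos <- matrix(NA_real_, n_tot, 2)
  for (l in 1:4) {
    pos[idsE[[l]], ] <- grid_xy(seq_len(nE), grid_e)
    pos[idsI[[l]], ] <- grid_xy(seq_len(nI), grid_i)
  }

  np <- default_neuron_params()
  net <- new_spiking_network(
    is_input = is_input, layer = layer, nclass = nclass, pos = pos,
    neuron_params = list(np$excitatory, np$inhibitory),
    syn_classes = scl, syn = syn,
    meta = list(kind = "four_layer", seed = seed, grid_e = grid_e,
                grid_i = grid_i, retina = retina, n_chan = n_chan,
                idsE = idsE, idsI = idsI))
  if (contacts_per_pair > 1) {
    net$syn <- expand_multi_contact(net$syn, contacts_per_pair,
                                    contact_delay_range)
    net$meta$contacts_per_pair <- contacts_per_pair
  }
  net
}

#' Expand a connection group to M synaptic contacts per pair
#'
#' Each plastic pre/post pair in `group` is replaced by `M` synapses with
#' independently sampled delays (from `delay_range`) and independent
#' initial weights, modelling an axon making several synaptic contacts
#' with different transmission delays on the same dendritic tree.
#' Non-plastic synapses are left untouched. `M = 1` returns the group
#' unchanged.
#'
#' @param group a `connection_group`.
#' @param M contacts per pair (positive integer).
#' @param delay_range delay range (ms) for the re-sampled contacts.
#' @param seed optional RNG seed.
#' @return A `connection_group`.
#' @export
expand_multi_contact <- function(group, M, delay_range = c(0, 10), seed = NULL) {
  stopifnot(M >= 1)
  if (M == 1) return(group)
  if (!is.null(seed)) set.seed(seed)
  pl <- group$plastic
  base <- group[pl, , drop = FALSE]
  reps <- base[rep(seq_len(nrow(base)), each = M), , drop = FALSE]
  n <- nrow(reps)
  reps$delay_ms <- sample_delays(n, delay_range)
  reps$weight <- stats::runif(n, 0, max(base$weight, 1e-12))
  out <- rbind(group[!pl, , drop = FALSE], reps)
  rownames(out) <- NULL
  class(out) <- c("connection_group", "data.frame")
  out
}
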