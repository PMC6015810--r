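#' Gaussian envelope width from octave bandwidth
#'
#' Standard relation between a Gabor filter's wavelength, half-amplitude
#' spatial-frequency bandwidth in octaves, and the envelope standard
#' deviation: `sigma = (lambda/pi) * sqrt(log(2)/2) * (2^b + 1)/(2^b - 1)`.
#'
#' @param lambda wavelength (pixels).
#' @param b bandwidth (octaves).
#' @return sigma (pixels).
#' @export
gabor_sigma <- function(lambda, b) {
  stopifnot(lambda > 0, b > 0)
  lambda / pi * sqrt(log(2) / 2) * (2^b + 1) / (2^b - 1)
}

#' Gabor filter parameter set
#'
#' @param lambda wavelength (pixels).
#' @param theta orientation (rad).
#' @param psi phase (rad).
#' @param b spatial bandwidth (octaves); fixes the envelope width `sigma`.
#' @param gamma aspect ratio.
#' @return An object of class `gabor_params` (with the derived `sigma`).
#' @export
gabor_params <- function(lambda = 2, theta = 0, psi = 0, b = 1.5,
                         gamma = 0.5) {
  structure(list(lambda = lambda, theta = theta, psi = psi, b = b,
                 gamma = gamma, sigma = gabor_sigma(lambda, b)),
            class = "gabor_params")
}

#' Evaluate a Gabor kernel on a square support
#'
#' `k(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) *
#' cos(2 pi x'/lambda + psi)` with `x' = x cos(theta) + y sin(theta)`,
#' `y' = -x sin(theta) + y cos(theta)`.
#'
#' @param params a [gabor_params()].
#' @param radius integer support radius in pixels (kernel is
#'   `(2*radius+1)^2`); must be at least `2 * sigma`.
#' @return Numeric matrix.
#' @export
gabor_kernel <- function(params, radius = max(2L, ceiling(2 * params$sigma))) {
  if (radius < 2 * params$sigma)
    stop("support radius must be at least 2*sigma")
  ax <- seq(-radius, radius)
  x <- matrix(ax, 2 * radius + 1, 2 * radius + 1)
  y <- t(x)
  xp <- x * cos(params$theta) + y * sin(params$theta)
  yp <- -x * sin(params$theta) + y * cos(params$theta)
  exp(-(xp^2 + params$gamma^2 * yp^2) / (2 * params$sigma^2)) *
    cos(2 * pi * xp / params$lambda + params$psi)
}

#' Default Gabor filter bank
#'
#' Four orientations (0, pi/4, pi/2, 3*pi/4) and two phases (0, pi) at
#' wavelength 2, bandwidth 1.5 octaves, aspect ratio 0.5 -- eight channels
#' per retinal location. The opposite-phase pair provides the ON/OFF
#' decomposition: their responses are elementwise negations, so after
#' half-rectification they partition signed filter output.
#'
#' @param thetas orientations (rad).
#' @param psis phases (rad).
#' @param lambda,b,gamma shared kernel parameters.
#' @return A list of [gabor_params()], class `gabor_bank`; channel order
#'   is phase-within-orientation.
#' @export
gabor_bank <- function(thetas = c(0, pi / 4, pi / 2, 3 * pi / 4),
                       psis = c(0, pi), lambda = 2, b = 1.5, gamma = 0.5) {
  bank <- list()
  for (th in thetas) for (ps in psis)
    bank[[length(bank) + 1L]] <- gabor_params(lambda, th, ps, b, gamma)
  class(bank) <- "gabor_bank"
  bank
}

#' Stimulus image container
#'
#' @param pixels numeric matrix with values in \[0, 1\].
#' @param label character label.
#' @return An object of class `stimulus_image`.
#' @export
stimulus_image <- function(pixels, label = "custom") {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels <= 1))
  structure(list(pixels = pixels, label = label), class = "stimulus_image")
}

# zero-padded 2-D convolution (kernel centred); kernels here are tiny
# (support ~5 px), so the shifted-add form is fast enough
conv2d <- function(img, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(0, h + 2L * kr, w + 2L * kr)
  pad[kr + seq_len(h), kr + seq_len(w)] <- img
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(kern))) for (j in seq_len(ncol(kern))) {
    kv <- kern[i, j]
    if (kv != 0)
      out <- out + kv * pad[(i - 1L) + seq_len(h), (j - 1L) + seq_len(w)]
  }
  out
}

#' Encode an image into input-layer firing rates
#'
#' Convolves each filter in the bank with the image, half-rectifies the
#' responses, normalizes by the maximum response across the whole bank for
#' this image, and scales to `max_rate` Hz. An all-zero image yields an
#' all-zero rate map. One input unit exists per (retinal location,
#' orientation, phase); unit indexing is channel-within-location, matching
#' the retinal input layer of [build_four_layer()].
#'
#' @param image a [stimulus_image()] (any square size).
#' @param bank a [gabor_bank()].
#' @param max_rate maximum input firing rate (Hz, default 100).
#' @return A `rate_map`: data.frame `(unit, rate_hz)` with attributes
#'   `retina_dim` (retina size) and `n_chan`.
#' @export
encode_image <- function(image, bank = gabor_bank(), max_rate = 100) {
  px <- image$pixels
  n_chan <- length(bank)
  resp <- lapply(bank, function(p) conv2d(px, gabor_kernel(p)))
  resp <- lapply(resp, function(r) pmax(r, 0))
  peak <- max(vapply(resp, max, numeric(1)))
  rates <- if (peak > 0) lapply(resp, function(r) r / peak * max_rate)
           else resp
  # unit id: channel-within-location, row-major over (x, y) cells
  n_loc <- length(px)
  rate_vec <- numeric(n_loc * n_chan)
  for (ch in seq_len(n_chan)) {
    # pixels are indexed column-major as (row=y? ), use [x, y] with x = row
    rate_vec[seq(ch, by = n_chan, length.out = n_loc)] <- as.numeric(rates[[ch]])
  }
  out <- data.frame(unit = seq_along(rate_vec), rate_hz = rate_vec)
  attr(out, "retina_dim") <- dim(px)
  attr(out, "n_chan") <- n_chan
  class(out) <- c("rate_map", "data.frame")
  out
}

#' Uniform-rate input drive
#'
#' Every input unit assigned the same firing rate; used for the flat
#' all-units-active stimulus of the two-layer experiments (1000 units at
#' 50 Hz).
#'
#' @param n_units number of input units.
#' @param rate firing rate (Hz).
#' @return A `rate_map`.
#' @export
make_flat_stimulus <- function(n_units, rate = 50) {
  stopifnot(n_units > 0, rate >= 0)
  out <- data.frame(unit = seq_len(n_units), rate_hz = rep(rate, n_units))
  class(out) <- c("rate_map", "data.frame")
  out
}

#' Realize Poisson spike trains from a rate map
#'
#' Each input unit emits a homogeneous Poisson train at its rate over
#' `[0, duration]`. Distinct seeds give independent realizations of the
#' same rate map; each realization is one "transform" of the stimulus.
#'
#' @param rates a `rate_map`.
#' @param duration presentation length (ms).
#' @param seed integer RNG seed for this realization.
#' @return data.frame `(neuron, time)` sorted by time (ms).
#' @export
generate_poisson_trains <- function(rates, duration, seed) {
  stopifnot(duration > 0)
  with_seed(seed, {
    lam <- rates$rate_hz * duration / 1000
    counts <- stats::rpois(length(lam), lam)
    neuron <- rep(rates$unit, counts)
    time <- stats::runif(sum(counts), 0, duration)
    ord <- order(time)
    data.frame(neuron = neuron[ord], time = time[ord])
  })
}

#' Programmatic outline stimuli: circle, heart, star
#'
#' Centered binary outline drawings on a `size x size` grid, emulating
#' the circle/heart/star training set. Outlines are traced parametrically
#' and rasterized with ~1.5 px stroke width.
#'
#' @param label one of `"circle"`, `"heart"`, `"star"`.
#' @param size image side (pixels; reference 128).
#' @return A [stimulus_image()].
#' @export
make_shape_image <- function(label = c("circle", "heart", "star"),
                             size = 128) {
  label <- match.arg(label)
  t <- seq(0, 2 * pi, length.out = 40 * size)
  r0 <- 0.35 * size
  cx <- (size + 1) / 2
  if (label == "circle") {
    x <- cx + r0 * cos(t); y <- cx + r0 * sin(t)
  } else if (label == "heart") {
    # classic cardioid-style heart curve, scaled to the same footprint
    xs <- 16 * sin(t)^3
    ys <- 13 * cos(t) - 5 * cos(2 * t) - 2 * cos(3 * t) - cos(4 * t)
    x <- cx + xs / 17 * r0
    y <- cx - ys / 17 * r0
  } else {
    # five-point star: alternate outer/inner radii, linear segments
    ang <- pi / 2 + seq(0, 2 * pi, length.out = 11)
    rad <- rep(c(r0, 0.45 * r0), length.out = 11)
    vx <- cx + rad * cos(ang); vy <- cx - rad * sin(ang)
    segs <- lapply(seq_len(10), function(i) {
      u <- seq(0, 1, length.out = 4 * size)
      cbind(vx[i] + u * (vx[i + 1] - vx[i]), vy[i] + u * (vy[i + 1] - vy[i]))
    })
    xy <- do.call(rbind, segs)
    x <- xy[, 1]; y <- xy[, 2]
  }
  px <- matrix(0, size, size)
  for (dx in c(-0.5, 0, 0.5)) for (dy in c(-0.5, 0, 0.5)) {
    ix <- pmin(pmax(round(x + dx), 1), size)
    iy <- pmin(pmax(round(y + dy), 1), size)
    px[cbind(ix, iy)] <- 1
  }
  stimulus_image(px, label)
}
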