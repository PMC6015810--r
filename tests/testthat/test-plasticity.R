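test_that("trace decay follows the exponential closed form", {
  pp <- plasticity_params(tau_c = 100, tau_d = 150)
  tr <- list(C = c(0, 0.5), D = 0.8)
  # zero is a fixed point
  out <- decay_traces(tr, 1000, pp)
  expect_equal(out$C[1], 0)
  # advancing by tau_c divides by e
  out <- decay_traces(tr, 100, pp)
  expect_equal(out$C[2], 0.5 / exp(1))
  expect_equal(out$D, 0.8 * exp(-100 / 150))
})

test_that("presynaptic arrival drives C and applies LTD from D", {
  pp <- plasticity_params(alpha_c = 0.5, rho = 0.1, tau_c = 100)
  tr <- list(C = 0, D = 0)
  w <- 0.7
  up <- on_presynaptic_arrival(1L, tr, w, pp, syn_post = 1L)
  expect_equal(up$traces$C, 0.5)          # alpha_c = 0.5 from rest
  expect_equal(up$weights, 0.7)           # D = 0: no LTD
  # second arrival exactly tau_c later: C = 0.5/e + 0.5 (1 - 0.5/e)
  tr2 <- decay_traces(up$traces, 100, pp)
  up2 <- on_presynaptic_arrival(1L, tr2, up$weights, pp, syn_post = 1L)
  expect_equal(up2$traces$C, 0.5 / exp(1) + 0.5 * (1 - 0.5 / exp(1)))
  # with D high the weight is depressed multiplicatively
  tr3 <- list(C = 0, D = 1)
  up3 <- on_presynaptic_arrival(1L, tr3, 0.7, pp, syn_post = 1L)
  expect_equal(up3$weights, 0.7 - 0.1 * 1 * 0.7)
})

test_that("postsynaptic spike applies the single-pair LTP closed form", {
  # pre arrival at t, post spike at t + 5 ms, tau_c = 100, rho = 0.1,
  # w = 0.5: dw = 0.1 * (0.5 e^-0.05) * (1 - 0.5)
  pp <- plasticity_params(alpha_c = 0.5, rho = 0.1, tau_c = 100)
  net <- single_neuron_net(weight = 0.5, plastic = TRUE)
  tr <- list(C = 0, D = 0)
  tr <- on_presynaptic_arrival(1L, tr, 0.5, pp, syn_post = 2L)$traces
  tr <- decay_traces(tr, 5, pp)
  up <- on_postsynaptic_spike(2L, tr, 0.5, net, pp)
  expect_equal(up$weights - 0.5, 0.1 * 0.5 * exp(-0.05) * 0.5)
  # no recent presynaptic activity: no weight change
  up0 <- on_postsynaptic_spike(2L, list(C = 0, D = c(0, 0)), 0.5, net, pp)
  expect_equal(up0$weights, 0.5)
  expect_equal(up0$traces$D[2], 0.5)
})

test_that("weights and traces stay in [0,1] over 10^4 random events", {
  pp <- plasticity_params(tau_c = 20, tau_d = 30)
  net <- single_neuron_net(weight = 0.5, plastic = TRUE, n_in = 10)
  w <- runif(10)
  tr <- list(C = runif(10), D = runif(11))
  set.seed(42)
  for (ev in 1:10000) {
    u <- runif(1)
    if (u < 0.45) {
      sid <- sample.int(10, 1)
      up <- on_presynaptic_arrival(sid, tr, w, pp, syn_post = net$syn$post)
      tr <- up$traces; w <- up$weights
    } else if (u < 0.9) {
      up <- on_postsynaptic_spike(11L, tr, w, net, pp)
      tr <- up$traces; w <- up$weights
    } else {
      tr <- decay_traces(tr, runif(1, 0.1, 20), pp)
    }
  }
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(tr$C >= 0 & tr$C <= 1))
  expect_true(all(tr$D >= 0 & tr$D <= 1))
})

test_that("pre-then-post potentiates, post-then-pre depresses", {
  pp <- plasticity_params(tau_c = 100, tau_d = 150)
  net <- single_neuron_net(weight = 0.5, plastic = TRUE)
  lag <- 5
  # oracle: direct evaluation of the two update formulas
  ltp_expect <- pp$rho * (pp$alpha_c * exp(-lag / pp$tau_c)) * 0.5
  ltd_expect <- pp$rho * (pp$alpha_d * exp(-lag / pp$tau_d)) * 0.5
  # pre -> post
  tr <- on_presynaptic_arrival(1L, list(C = 0, D = 0), 0.5, pp,
                               syn_post = 2L)$traces
  tr <- decay_traces(tr, lag, pp)
  w_ltp <- on_postsynaptic_spike(2L, tr, 0.5, net, pp)$weights
  expect_equal(w_ltp - 0.5, ltp_expect)
  expect_gt(w_ltp, 0.5)
  # post -> pre
  tr <- on_postsynaptic_spike(2L, list(C = 0, D = c(0, 0)), 0.5, net,
                              pp)$traces
  tr <- decay_traces(tr, lag, pp)
  up <- on_presynaptic_arrival(1L, tr, 0.5, pp, syn_post = 2L)
  expect_equal(0.5 - up$weights, ltd_expect)
  expect_lt(up$weights, 0.5)
})

test_that("repeated pairing saturates softly at the bounds", {
  pp <- plasticity_params(tau_c = 100, tau_d = 150)
  net <- single_neuron_net(weight = 0.5, plastic = TRUE)
  w <- 0.5
  for (k in 1:200) {
    tr <- on_presynaptic_arrival(1L, list(C = 0, D = c(0, 0)), w, pp,
                                 syn_post = 2L)$traces
    tr <- decay_traces(tr, 2, pp)
    w <- on_postsynaptic_spike(2L, tr, w, net, pp)$weights
  }
  expect_gt(w, 0.99); expect_lte(w, 1)
  w <- 0.5
  for (k in 1:200) {
    tr <- on_postsynaptic_spike(2L, list(C = 0, D = c(0, 0)), w, net,
                                pp)$traces
    tr <- decay_traces(tr, 2, pp)
    w <- on_presynaptic_arrival(1L, tr, w, pp, syn_post = 2L)$weights
  }
  expect_lt(w, 0.01); expect_gte(w, 0)
})

test_that("shifting a delay equals shifting the presynaptic spike time", {
  # the arrival-locked LTP depends only on arrival time = emission + delay
  pp <- plasticity_params(tau_c = 50, tau_d = 50)
  base <- function(delay, t_pre) {
    np <- default_neuron_params()$excitatory
    # input 1: plastic weak synapse under test; input 2: strong driver
    syn <- connection_group(pre = c(1L, 2L), post = c(3L, 3L),
                            weight = c(0.5, 1), delay_ms = c(delay, 0.5),
                            class_id = c(1L, 2L), plastic = c(TRUE, FALSE))
    net <- polybind:::new_spiking_network(
      is_input = c(TRUE, TRUE, FALSE), layer = c(0L, 0L, 1L),
      nclass = c(0L, 0L, 1L), pos = NULL, neuron_params = list(np),
      syn_classes = list(
        weak = synapse_class_params("weak", 2, 0, 0.1, TRUE),
        drive = synapse_class_params("drive", 0.3, 0, 1000, FALSE)),
      syn = syn)
    res <- run_trial(net, data.frame(neuron = c(1L, 2L), time = c(t_pre, 20)),
                     40, 0.02, plasticity = pp, plasticity_on = TRUE)
    res$weights[1]
  }
  expect_equal(base(delay = 6, t_pre = 4), base(delay = 2, t_pre = 8))
  expect_equal(base(delay = 9, t_pre = 3), base(delay = 1, t_pre = 11))
})
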