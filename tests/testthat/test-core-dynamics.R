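test_that("membrane time constants derive from capacitance and leak", {
  np <- default_neuron_params()
  expect_equal(np$excitatory$tau_m, 20)
  # inhibitory: derived 214/18 = 11.89 ms, within 1% of the quoted 12 ms
  expect_equal(np$inhibitory$tau_m, 214 / 18)
  expect_lt(abs(np$inhibitory$tau_m - 12) / 12, 0.01)
  expect_error(neuron_class_params(500, 25, -53, -74, -57, 2),
               "threshold")
})

test_that("resting potential is a fixed point and leak decay is monotone", {
  net <- single_neuron_net()
  st <- new_sim_state(net)
  for (k in 1:100) st <- integrate_step(st, net, 0.02)
  expect_equal(st$V[2], -74)
  # displaced potential decays monotonically back toward rest
  st$V[2] <- -60
  path <- numeric(200)
  for (k in 1:200) { st <- integrate_step(st, net, 0.02); path[k] <- st$V[2] }
  expect_true(all(diff(abs(path - (-74))) <= 0))
})

test_that("constant conductance drive converges to the closed-form voltage", {
  net <- single_neuron_net()
  np <- net$neuron_params[[1]]
  st <- new_sim_state(net)
  st$g[1] <- 10                      # held constant: no decay applied
  for (k in seq_len(200 / 0.02)) st <- integrate_step(st, net, 0.02)
  expect_lt(abs(st$V[2] - lif_steady_state(np, 10)), 0.1)
})

test_that("conductance decay is exponential and arrivals add lambda*dg", {
  net <- single_neuron_net(weight = 0.5, g_scale = 1.6, tau_g = 2)
  st <- new_sim_state(net)
  st$g[1] <- 1
  for (k in seq_len(2 / 0.02)) st <- update_conductances(st, net, integer(0), 0.02)
  expect_equal(st$g[1], exp(-1), tolerance = 1e-12)
  # single arrival on scaling bound 1.6, weight 0.5 -> jump 0.8 nS
  g_before <- st$g[1]
  st <- update_conductances(st, net, 1L, 0)
  expect_equal(st$g[1] - g_before, 1.6 * 0.5)
  expect_error(update_conductances(st, net, 99L, 0.02), "unknown synapse")
})

test_that("default inhibitory loop time constants are 2 and 5 ms", {
  scl <- default_synapse_classes()
  expect_equal(scl$ElI$tau_g, 2)
  expect_equal(scl$IlE$tau_g, 5)
  expect_equal(scl$EfE$V_rev, 0)
  expect_equal(scl$IlE$V_rev, -70)
})

test_that("threshold crossing emits one spike, resets and is refractory", {
  net <- single_neuron_net()
  st <- new_sim_state(net)
  st$V[2] <- -53
  st$t <- 1; st$step <- as.integer(1 / 0.02)
  det <- detect_spikes_and_reset(st, net, 0.02)
  expect_equal(nrow(det$events), 1)
  expect_equal(det$state$V[2], -57)
  expect_equal(det$state$refr_steps[2], as.integer(2 / 0.02))
  # below threshold: no spike, V untouched
  st2 <- new_sim_state(net); st2$V[2] <- -60
  det2 <- detect_spikes_and_reset(st2, net, 0.02)
  expect_equal(nrow(det2$events), 0)
  expect_equal(det2$state$V[2], -60)
})

test_that("inter-spike interval under constant drive matches the analytic LIF period", {
  # constant drive approximated by a high-rate regular input on a slow synapse
  np <- default_neuron_params()$excitatory
  g_drive <- 30
  dt <- 0.02
  net <- single_neuron_net(weight = 1, delay = 1, g_scale = g_drive,
                           tau_g = 1e9)   # effectively non-decaying
  res <- run_trial(net, data.frame(neuron = 1L, time = 0.5),
                   duration = 60, dt = dt)
  isis <- diff(res$spikes$time[res$spikes$neuron == 2])
  expect_gt(length(isis), 3)
  expect_lt(max(abs(isis - lif_isi(np, g_drive))), 2 * dt)
})

test_that("delay line delivers at emission + delay, in sorted order", {
  net <- random_small_net(11)
  dt <- 0.02
  # brute-force oracle: all (arrival, id) pairs sorted
  set.seed(99)
  ev <- data.frame(neuron = sample(seq_len(4), 1000, replace = TRUE),
                   time = 0, step = sample.int(5000, 1000, replace = TRUE))
  line <- data.frame(syn_id = integer(), arrival_step = integer())
  line <- schedule_deliveries(ev, net, line, dt)
  brute <- do.call(rbind, lapply(seq_len(nrow(ev)), function(r) {
    sid <- which(net$syn$pre == ev$neuron[r])
    data.frame(syn_id = sid,
               arrival_step = ev$step[r] +
                 pmax(1L, as.integer(round(net$syn$delay_ms[sid] / dt))))
  }))
  brute <- brute[order(brute$arrival_step, brute$syn_id), ]
  expect_equal(line$syn_id, brute$syn_id)
  expect_equal(line$arrival_step, brute$arrival_step)
})

test_that("a single input spike produces the hand-traced output spike", {
  # scalar hand simulation of the same equations, independent loop
  np <- default_neuron_params()$excitatory
  g_scale <- 300; tau_g <- 2; w <- 1; delay <- 1.5; t_in <- 5; dt <- 0.02
  V <- np$V_0; g <- 0; t_spike <- NA
  arrive_step <- floor(t_in / dt) + round(delay / dt)
  for (k in 0:(30 / dt)) {
    if (k == arrive_step) g <- g + g_scale * w
    I <- g * (0 - V)
    V <- V + dt / np$tau_m * ((np$V_0 - V) + I / np$g_0)
    if (V >= np$theta) { t_spike <- (k + 1) * dt; break }
    g <- g * exp(-dt / tau_g)
  }
  net <- single_neuron_net(weight = w, delay = delay, g_scale = g_scale,
                           tau_g = tau_g)
  res <- run_trial(net, data.frame(neuron = 1L, time = t_in), 30, dt)
  expect_gte(nrow(res$spikes), 1)
  expect_equal(res$spikes$time[1], t_spike)
})

test_that("runs are deterministic and both engines agree", {
  net <- random_small_net(7)
  ins <- random_inputs(3, 4, 80, 50)
  a <- run_trial(net, ins, 50, 0.02)
  b <- run_trial(net, ins, 50, 0.02)
  expect_identical(a$spikes, b$spikes)
  r <- run_trial(net, ins, 50, 0.02, engine = "r")
  expect_equal(a$spikes$neuron, r$spikes$neuron)
  expect_equal(a$spikes$time, r$spikes$time)
  expect_equal(a$V[!net$is_input], r$V[!net$is_input], tolerance = 1e-10)
  # with plasticity on, weights and rasters also agree
  pp <- plasticity_params(tau_c = 20, tau_d = 30)
  ap <- run_trial(net, ins, 50, 0.02, plasticity = pp, plasticity_on = TRUE)
  rp <- run_trial(net, ins, 50, 0.02, plasticity = pp, plasticity_on = TRUE,
                  engine = "r")
  expect_equal(ap$spikes$time, rp$spikes$time)
  expect_equal(ap$weights, rp$weights, tolerance = 1e-10)
})

test_that("conductances stay non-negative for arbitrary spike schedules", {
  net <- random_small_net(5)
  st <- new_sim_state(net)
  set.seed(1)
  for (k in 1:500) {
    arr <- which(runif(nrow(net$syn)) < 0.1)
    st <- update_conductances(st, net, arr, 0.05)
    expect_true(all(st$g >= 0))
  }
})

test_that("halving dt barely moves first-spike times", {
  net <- single_neuron_net(weight = 1, delay = 1, g_scale = 40, tau_g = 50)
  ins <- data.frame(neuron = 1L, time = 2)
  t4 <- run_trial(net, ins, 40, 0.04)$spikes$time[1]
  t2 <- run_trial(net, ins, 40, 0.02)$spikes$time[1]
  expect_lt(abs(t4 - t2), 0.05)
})

test_that("run_trial contracts: empty input, bounds checks, rounding", {
  net <- single_neuron_net()
  empty <- data.frame(neuron = integer(), time = numeric())
  res <- run_trial(net, empty, 10, 0.02)
  expect_equal(nrow(res$spikes), 0)
  expect_equal(res$V[2], -74)
  expect_error(run_trial(net, data.frame(neuron = 2L, time = 1), 10, 0.02),
               "input-layer")
  expect_error(run_trial(net, data.frame(neuron = 1L, time = 50), 10, 0.02),
               "within")
  expect_warning(run_trial(net, empty, 10.01, 0.02), "rounded down")
})
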