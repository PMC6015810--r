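test_that("rate binning follows the equal-width, zero-to-bin-0 rule", {
  tb <- response_table(cell = 1, stimulus = c("a", "a", "b"),
                       transform = c(1, 2, 1), rate = c(0, 50, 100))
  b <- bin_responses(tb, 2)
  expect_equal(b$bin, c(0, 0, 1))
  # all responses equal: a single bin
  tb2 <- response_table(1, c("a", "b"), c(1, 1), c(7, 7))
  expect_length(unique(bin_responses(tb2, 5)$bin), 1)
  # idempotence: re-binning binned labels with the same n_bins
  b$rate <- b$bin
  expect_equal(bin_responses(b, 2)$bin, b$bin)
  b10 <- data.frame(cell = 1, rate = 0:9)
  expect_equal(bin_responses(b10, 10)$bin, 0:9)
})

test_that("perfectly selective cells attain the log2(n) ceiling", {
  # unique bin for every transform of exactly one of three stimuli
  tb <- response_table(cell = 1,
                       stimulus = rep(c("a", "b", "c"), each = 4),
                       transform = rep(1:4, 3),
                       rate = c(rep(80, 4), rep(0, 8)))
  info <- stimulus_specific_information(bin_responses(tb, 10))
  expect_equal(max(info$per_stimulus$info_bits), log2(3))
  expect_equal(info$per_cell$max_info_bits, log2(3))
  expect_equal(info$ceiling_bits, max_information(3))
  expect_equal(max_information(3), log2(3))
})

test_that("information matches hand-evaluated cases and vanishes for flat responses", {
  # identical response distribution under all stimuli: zero bits
  tb0 <- response_table(1, rep(c("a", "b"), each = 3), rep(1:3, 2),
                        rep(c(10, 20, 30), 2))
  info0 <- stimulus_specific_information(bin_responses(tb0, 10))
  expect_equal(info0$per_stimulus$info_bits, c(0, 0))
  # bin 1 always under A; bins 1/2 with prob 1/2 under B:
  # I(A) = log2(1/0.75)
  tb1 <- data.frame(cell = 1,
                    stimulus = c("A", "A", "B", "B"),
                    transform = c(1, 2, 1, 2),
                    rate = c(1, 1, 1, 2), bin = c(1, 1, 1, 2))
  info1 <- stimulus_specific_information(tb1)
  ia <- info1$per_stimulus$info_bits[info1$per_stimulus$stimulus == "A"]
  expect_equal(ia, log2(1 / 0.75))
})

test_that("information is non-negative, bounded, and killed by label shuffles", {
  set.seed(3)
  for (rep in 1:5) {
    n_s <- sample(2:4, 1); n_t <- 8
    tb <- response_table(cell = rep(1:3, each = n_s * n_t),
                         stimulus = rep(rep(letters[1:n_s], each = n_t), 3),
                         transform = rep(rep(1:n_t, n_s), 3),
                         rate = runif(3 * n_s * n_t, 0, 50))
    info <- stimulus_specific_information(bin_responses(tb, 5))
    expect_true(all(info$per_stimulus$info_bits >= -1e-12))
    expect_true(all(info$per_stimulus$info_bits <= log2(n_s) + 1e-9))
    expect_true(all(sort(info$per_cell$rank) == 1:3))
  }
  # permutation control: shuffling stimulus labels drives median info to ~0
  tb <- response_table(cell = rep(1:20, each = 9),
                       stimulus = rep(rep(c("a", "b", "c"), each = 3), 20),
                       transform = rep(rep(1:3, 3), 20),
                       rate = rep(c(60, 0, 0), each = 3, times = 20))
  real <- stimulus_specific_information(bin_responses(tb, 5))
  set.seed(4)
  tb_sh <- tb
  tb_sh$stimulus <- unlist(lapply(split(tb$stimulus, tb$cell), sample))
  sh <- stimulus_specific_information(bin_responses(tb_sh, 5))
  expect_gt(stats::median(real$per_cell$max_info_bits), 1.5)
  expect_lt(stats::median(sh$per_cell$max_info_bits),
            stats::median(real$per_cell$max_info_bits) / 2)
})

test_that("spike-pair table marks lags within the 10 ms window only", {
  # neuron 2 fires 3 ms after neuron 1 in every transform of stimulus a;
  # far outside the window under stimulus b
  mk <- function(stim, tfm, lag)
    data.frame(stimulus = stim, transform = tfm,
               neuron = c(1L, 2L), time = c(10, 10 + lag))
  rec <- rbind(mk("a", 1, 3), mk("a", 2, 3), mk("a", 3, 3),
               mk("b", 1, 40), mk("b", 2, 40), mk("b", 3, 40),
               mk("c", 1, 25), mk("c", 2, 25), mk("c", 3, 25))
  tab <- build_pair_png_table(rec)
  # the only in-window ordered pair is (j=1, i=2, d=3)
  hit <- tab[tab$prob > 0, ]
  expect_true(all(hit$j == 1 & hit$i == 2 & hit$d == 3))
  expect_true(all(hit$stimulus == "a"))
  expect_true(all(tab$d >= 0 & tab$d <= 9))
  # present in all transforms of one of three stimuli: ceiling information
  info <- pair_png_information(tab)
  expect_equal(info$max_info_bits, log2(3))
  expect_equal(info$best_stimulus, "a")
})

test_that("equally probable pairs carry zero bits", {
  mk <- function(stim, tfm)
    data.frame(stimulus = stim, transform = tfm,
               neuron = c(1L, 2L), time = c(5, 8))
  rec <- do.call(rbind, lapply(c("a", "b"), function(s)
    do.call(rbind, lapply(1:4, function(k) mk(s, k)))))
  info <- pair_png_information(build_pair_png_table(rec))
  expect_equal(info$max_info_bits, 0)
})

test_that("first-spike statistics follow the all-trials inclusion rule", {
  rec <- data.frame(trial = c(1, 1, 2, 2, 1, 2, 2),
                    neuron = c(1, 2, 1, 2, 3, 3, 1),
                    time = c(5, 4, 7, 4, 9, 11, 30))
  fs <- first_spike_statistics(rec)
  # neuron 1: first spikes {5, 7}: mean 6, sd sqrt(2) (n-1 convention)
  r1 <- fs[fs$neuron == 1, ]
  expect_equal(r1$mean_ms, 6)
  expect_equal(r1$sd_ms, sqrt(2))
  # identical times across trials: zero sd
  expect_equal(fs$sd_ms[fs$neuron == 2], 0)
  # a neuron silent in one trial is excluded
  rec2 <- rbind(rec, data.frame(trial = 3, neuron = c(1, 2), time = c(6, 4)))
  fs2 <- first_spike_statistics(rec2)
  expect_false(3 %in% fs2$neuron)
  expect_error(first_spike_statistics(rec[rec$trial == 1, ]), "two trials")
})

test_that("binding-circuit detection equals brute-force triple enumeration", {
  # constructed triple satisfying the delay relation exactly
  np <- default_neuron_params()$excitatory
  mknet <- function(syn) polybind:::new_spiking_network(
    is_input = rep(FALSE, max(syn$post, syn$pre)),
    layer = rep(1L, max(syn$post, syn$pre)),
    nclass = rep(1L, max(syn$post, syn$pre)), pos = NULL,
    neuron_params = list(np),
    syn_classes = list(synapse_class_params("EfE", 150, 0, 1.6, TRUE)),
    syn = syn)
  syn <- connection_group(pre = c(1, 1, 2), post = c(2, 3, 3),
                          weight = 1, delay_ms = c(3, 6, 3),
                          class_id = 1L, plastic = TRUE)
  hits <- find_binding_circuits(mknet(syn), weight_threshold = 0.5,
                                delay_tolerance = 1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$residual_ms, 0)
  expect_equal(unlist(hits[1, c("low", "high", "binder")]),
               c(low = 1, high = 2, binder = 3))
  # residual 2 ms > tolerance 1 ms: not detected
  syn$delay_ms[2] <- 8
  expect_equal(nrow(find_binding_circuits(mknet(syn), 0.5, 1)), 0)
  # random networks vs exhaustive enumeration over all ordered triples
  for (seed in 1:3) {
    set.seed(seed)
    n <- 40
    m <- 300
    syn <- connection_group(pre = sample.int(n, m, TRUE),
                            post = sample.int(n, m, TRUE),
                            weight = runif(m), delay_ms = runif(m, 0.1, 10),
                            class_id = 1L, plastic = TRUE)
    syn <- syn[syn$pre != syn$post, ]
    net <- mknet(syn)
    got <- find_binding_circuits(net, weight_threshold = 0.5,
                                 delay_tolerance = 1)
    strong <- syn[syn$weight >= 0.5, ]
    brute <- 0L
    for (r12 in seq_len(nrow(strong))) for (r23 in seq_len(nrow(strong))) {
      if (strong$post[r12] != strong$pre[r23]) next
      a <- strong$pre[r12]; b <- strong$post[r12]; c3 <- strong$post[r23]
      if (a == c3) next
      r13 <- which(strong$pre == a & strong$post == c3)
      for (k in r13) {
        res <- abs(strong$delay_ms[k] -
                     (strong$delay_ms[r12] + strong$delay_ms[r23]))
        if (res <= 1) brute <- brute + 1L
      }
    }
    expect_equal(nrow(got), brute)
  }
})

test_that("the binder fires iff causally driven through the delay relation", {
  good <- list(d21 = 3, d31 = 6, d32 = 3)
  v <- verify_binding_behavior(good)
  expect_true(as.logical(v))
  expect_true(attr(v, "causal_fired"))
  expect_false(attr(v, "noncausal_fired"))
  # violating the delay relation breaks the causal condition
  bad <- list(d21 = 3, d31 = 9, d32 = 3)
  vb <- verify_binding_behavior(bad)
  expect_false(as.logical(vb))
  expect_false(attr(vb, "causal_fired"))
})

test_that("the binder's coincidence window matches an offset sweep", {
  # drive neurons 1 and 2 independently; binder fires only when its two
  # afferent volleys arrive within the coincidence window
  offs <- c(-6, -4, -2, -1, 0, 1, 2, 4, 6)
  net <- make_binding_probe_network(3, 6, 3, drive12 = FALSE)
  fired <- vapply(offs, function(off) {
    ins <- data.frame(neuron = c(1L, 2L), time = c(5, 8 + off))
    res <- run_trial(net, ins, 40, 0.02)
    any(res$spikes$neuron == 5L)
  }, logical(1))
  expect_true(all(fired[abs(offs) <= 1]))
  expect_false(any(fired[abs(offs) >= 4]))
})
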