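test_that("default topology matches the reservoir recipe", {
  topo <- build_network(seed = 1)
  expect_equal(topo$n_reservoir, 1000)
  expect_equal(topo$n_inhibitory, 200)
  expect_equal(topo$n_excitatory, 800)
  # every neuron has exactly `fanout` outgoing edges
  expect_true(all(colSums(!is.na(topo$targets)) == 100))
  expect_equal(dim(topo$targets), c(100, 1000))
  # no inhibitory -> inhibitory edge
  inh_targets <- topo$targets[, topo$inhibitory_ids]
  expect_true(all(inh_targets %in% topo$excitatory_ids))
  # weight signs and ranges
  expect_true(all(topo$tweights[, topo$excitatory_ids] >= 0 &
                  topo$tweights[, topo$excitatory_ids] <= 1))
  expect_true(all(topo$tweights[, topo$inhibitory_ids] >= -1 &
                  topo$tweights[, topo$inhibitory_ids] <= 0))
  # output neurons are excitatory; motor pool split in half
  expect_true(all(topo$output_ids %in% topo$excitatory_ids))
  expect_length(topo$agonist_ids, 100)
  expect_length(topo$antagonist_ids, 100)
})

test_that("topology invariants hold across a 20-seed sweep", {
  for (seed in 1:20) {
    topo <- build_network(seed, n_reservoir = 100, n_inhibitory = 20,
                          n_output = 20, n_motor = 20, fanout = 10)
    expect_true(all(topo$targets[, topo$inhibitory_ids] %in%
                    topo$excitatory_ids))
    # no self-edges, no duplicate targets per neuron
    for (j in seq_len(100)) {
      expect_false(any(topo$targets[, j] == j))
      expect_equal(anyDuplicated(topo$targets[, j]), 0L)
    }
    expect_true(all(topo$output_ids %in% topo$excitatory_ids))
  }
})

test_that("identical seed gives identical topology; bad configs error", {
  t1 <- build_network(3, n_reservoir = 80, n_inhibitory = 16,
                      n_output = 16, n_motor = 16, fanout = 10)
  t2 <- build_network(3, n_reservoir = 80, n_inhibitory = 16,
                      n_output = 16, n_motor = 16, fanout = 10)
  expect_identical(t1$targets, t2$targets)
  expect_identical(t1$tweights, t2$tweights)
  expect_identical(t1$output_ids, t2$output_ids)

  expect_error(build_network(1, n_reservoir = 100, n_inhibitory = 100,
                             n_output = 10, n_motor = 10, fanout = 10),
               "n_inhibitory")
  expect_error(build_network(1, n_reservoir = 100, n_inhibitory = 20,
                             n_output = 10, n_motor = 10, fanout = 100),
               "fanout")
  expect_error(build_network(1, n_reservoir = 100, n_inhibitory = 20,
                             n_output = 90, n_motor = 90, fanout = 10),
               "excitatory")
})

test_that("noise stream is bounded, centered, and reproducible", {
  x <- sample_noise(1e6, seed = 11)
  expect_true(max(abs(x)) <= 6.5)
  expect_lt(abs(mean(x)), 0.02)
  expect_identical(sample_noise(1000, seed = 5), sample_noise(1000, seed = 5))
})

test_that("a resting regular-spiking neuron stays silent with no input", {
  topo <- tiny_topology()
  topo$tweights[] <- 0
  state <- init_network_state(topo)
  s <- matrix(0, topo$n_output, topo$n_motor)
  for (t in 1:200) {
    out <- step_network(state, topo, s, rep(0, topo$n_reservoir + topo$n_motor))
    state <- out$state
    expect_false(any(out$spikes_res))
    expect_false(any(out$spikes_mot))
  }
})

test_that("a neuron at or above 30 mV at step entry spikes and resets", {
  topo <- tiny_topology()
  state <- init_network_state(topo)
  state$v_res[1] <- 31
  u_before <- state$u_res[1]
  out <- step_network(state, topo, matrix(0, 10, 10), rep(0, 70))
  expect_true(out$spikes_res[1])
  # reset applied before integration: v restarted from c
  expect_lt(out$state$v_res[1], 0)
  expect_equal(out$state$u_res[1],
               (u_before + topo$d_reset[1]) +
                 topo$a[1] * (topo$b[1] * out$state$v_res[1] -
                              (u_before + topo$d_reset[1])),
               tolerance = 1e-12)
})

test_that("driven single neuron matches the scalar oracle spike count", {
  # one regular-spiking neuron under constant 10 pA for 1000 ms
  oracle <- izh_scalar(0.02, 0.2, -65, 8, rep(10, 1000))
  expect_gt(sum(oracle$spikes), 0)

  topo <- build_network(5, n_reservoir = 10, n_inhibitory = 2, n_output = 2,
                        n_motor = 2, fanout = 3)
  topo$tweights[] <- 0   # isolate neurons
  state <- init_network_state(topo)
  s <- matrix(0, 2, 2)
  noise <- c(10, rep(0, 9), 0, 0)
  spikes <- logical(1000)
  for (t in 1:1000) {
    out <- step_network(state, topo, s, noise)
    state <- out$state
    spikes[t] <- out$spikes_res[1]
  }
  expect_equal(sum(spikes), sum(oracle$spikes))
})

test_that("vectorized stepping equals the per-neuron scalar oracle", {
  topo <- build_network(9, n_reservoir = 10, n_inhibitory = 2, n_output = 4,
                        n_motor = 4, fanout = 3)
  sv <- init_network_state(topo)
  ss <- init_network_state(topo)
  set.seed(21)
  s <- matrix(runif(4 * 4), 4, 4)
  max_dev <- 0
  for (t in 1:1000) {
    noise <- runif(14, -6.5, 6.5)
    ov <- step_network(sv, topo, s, noise)
    os <- step_network_scalar(ss, topo, s, noise)
    sv <- ov$state
    ss <- os$state
    expect_identical(ov$spikes_res, os$spikes_res)
    max_dev <- max(max_dev, abs(sv$v_res - ss$v_res), abs(sv$u_res - ss$u_res),
                   abs(sv$v_mot - ss$v_mot), abs(sv$u_mot - ss$u_mot))
  }
  expect_lt(max_dev, 1e-9)
})
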