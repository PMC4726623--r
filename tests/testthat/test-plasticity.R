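make_plast <- function(n_out = 4, n_mot = 4, seed = 1) {
  topo <- list(n_output = n_out, n_motor = n_mot)
  init_plasticity(topo, seed = seed)
}

test_that("fresh plasticity state is zeroed with U(0,1) weights", {
  topo <- list(n_output = 200, n_motor = 200)
  st <- init_plasticity(topo, seed = 3)
  expect_equal(st$d, 0)
  expect_true(all(st$e == 0))
  expect_true(all(st$c == 0))
  expect_true(all(st$s >= 0 & st$s <= 1))
  expect_lt(abs(mean(st$s) - 0.5), 0.01)
})

test_that("dopamine decays by 0.995 per ms and bumps by 1 per reward", {
  st <- make_plast()
  st$d <- 1
  st <- per_ms_update(st, rep(FALSE, 4), rep(FALSE, 4), t_ms = 1)
  expect_equal(st$d, 0.995)

  st$d <- 0
  st <- deliver_reward(st)
  expect_equal(st$d, 1)
  st$d <- 0.4
  st <- deliver_reward(st)
  expect_equal(st$d, 1.4)

  # two rewards separated by 1000 ms of decay: closed form 1 + 0.995^1000
  st <- make_plast()
  st <- deliver_reward(st)
  for (t in 1:1000)
    st <- per_ms_update(st, rep(FALSE, 4), rep(FALSE, 4), t_ms = t,
                        reward = (t == 1000))
  expect_equal(st$d, 1 + exp(1000 * log(0.995)), tolerance = 1e-12)
})

test_that("presynaptic trace is set to 0.1 then decays by 0.95 within the ms", {
  st <- make_plast()
  out_spk <- c(TRUE, FALSE, FALSE, FALSE)
  st <- per_ms_update(st, out_spk, rep(FALSE, 4), t_ms = 1)
  expect_equal(st$c[1], 0.1 * 0.95)
  expect_true(all(st$c[-1] == 0))
})

test_that("weight update caps at 4 before normalizing to mean 1", {
  st <- make_plast(2, 1)
  st$s <- matrix(c(3.9, 1), 2, 1)
  st$e <- matrix(c(0.5, 0), 2, 1)
  st$d <- 1
  st2 <- apply_weight_update(st)
  # pre-normalization strengths: min(3.9 + 0.5, 4) = 4 and 1
  expect_equal(st2$s, matrix(c(4, 1) / mean(c(4, 1)), 2, 1))
  expect_equal(mean(st2$s), 1, tolerance = 1e-12)
  # eligibility decayed by 0.99 after the update
  expect_equal(st2$e, st$e * 0.99)
})

test_that("eligibility decays by 0.99 per update with no spikes", {
  st <- make_plast()
  st$e[] <- 1
  st <- per_ms_update(st, rep(FALSE, 4), rep(FALSE, 4), t_ms = 10)
  expect_true(all(st$e == 0.99))
})

test_that("without dopamine, weights change only by normalization", {
  st <- make_plast(6, 6, seed = 8)
  ranks0 <- rank(st$s)
  set.seed(99)
  for (t in 1:300) {
    st <- per_ms_update(st, runif(6) < 0.1, runif(6) < 0.1, t_ms = t)
  }
  expect_equal(st$d, 0)
  expect_equal(mean(st$s), 1, tolerance = 1e-9)
  expect_identical(rank(st$s), ranks0)   # ordering preserved when d = 0
  expect_true(min(st$s) >= 0)
})

test_that("normalization by the grand sum is available but collapses scale", {
  p <- plasticity_params(normalize = "sum")
  st <- make_plast(4, 4)
  st <- apply_weight_update(st, p)
  expect_equal(sum(st$s), 1, tolerance = 1e-12)
})

test_that("eligibility oracle worked examples", {
  expect_equal(eligibility_oracle(c(5), integer(0), 20), 0)
  expect_equal(eligibility_oracle(c(5), c(7), 9), 0.1 * 0.95^2)
  # same-ms pairing does not potentiate (trace read before registration)
  expect_equal(eligibility_oracle(c(7), c(7), 9), 0)
  # a boundary at the post-spike ms itself decays the fresh increment
  expect_equal(eligibility_oracle(c(8), c(10), 10), 0.1 * 0.95^2 * 0.99)
  expect_error(eligibility_oracle(c(5, 3), c(7), 9), "sorted")
})

test_that("incremental eligibility equals the brute-force oracle", {
  params <- plasticity_params()
  set.seed(14)
  for (case in 1:100) {
    horizon <- 200
    pre <- sort(sample(horizon, rbinom(1, 20, 0.5)))
    post <- sort(sample(horizon, rbinom(1, 20, 0.5)))
    st <- list(d = 0, c = 0, e = matrix(0, 1, 1), s = matrix(0.5, 1, 1))
    for (t in seq_len(horizon)) {
      st <- per_ms_update(st, t %in% pre, t %in% post, t_ms = t, params)
    }
    expect_equal(st$e[1, 1],
                 eligibility_oracle(pre, post, horizon, params),
                 tolerance = 1e-12)
  }
})

test_that("plasticity invariants hold under random spiking with rewards", {
  st <- make_plast(8, 8, seed = 2)
  set.seed(31)
  for (t in 1:2000) {
    st <- per_ms_update(st, runif(8) < 0.05, runif(8) < 0.05, t_ms = t,
                        reward = runif(1) < 0.002)
    expect_true(min(st$s) >= 0)
    if (t %% 10 == 0) {
      # potentiation only adds, so the pre-normalization mean is >= 1 and
      # the capped maximum cannot grow past 4 through normalization
      expect_true(max(st$s) <= 4 + 1e-9)
      expect_equal(mean(st$s), 1, tolerance = 1e-9)
    }
  }
})
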