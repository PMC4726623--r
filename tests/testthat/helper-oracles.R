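# Independent reference implementations used as oracles. These deliberately
# mirror the model definitions with the simplest possible code (per-neuron
# scalar loops, naive O(n*w) smoothing) and stay independent of the
# vectorized / compiled paths they check.

# Scalar Izhikevich neuron: per-ms update with entry-detection and reset,
# two half-ms sub-steps for v, driven by a per-ms input current sequence.
izh_scalar <- function(a, b, c, d_reset, I, v0 = -65, u0 = b * v0) {
  n <- length(I)
  v <- v0
  u <- u0
  spikes <- logical(n)
  v_trace <- u_trace <- numeric(n)
  for (t in seq_len(n)) {
    if (v >= 30) {
      spikes[t] <- TRUE
      v <- c
      u <- u + d_reset
    }
    for (half in 1:2) v <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u + I[t])
    u <- u + a * (b * v - u)
    v_trace[t] <- v
    u_trace[t] <- u
  }
  list(spikes = spikes, v = v_trace, u = u_trace)
}

# Scalar network stepper: same update, full network, per-neuron loops.
# state mirrors init_network_state(); one call = one ms.
step_network_scalar <- function(state, topology, plastic_weights, noise) {
  n <- topology$n_reservoir
  m <- topology$n_motor
  mp <- topology$motor_params
  fired_res <- logical(n)
  for (i in seq_len(n)) {
    if (state$v_res[i] >= 30) {
      fired_res[i] <- TRUE
      state$v_res[i] <- topology$c[i]
      state$u_res[i] <- state$u_res[i] + topology$d_reset[i]
    }
  }
  fired_mot <- logical(m)
  for (i in seq_len(m)) {
    if (state$v_mot[i] >= 30) {
      fired_mot[i] <- TRUE
      state$v_mot[i] <- mp$c
      state$u_mot[i] <- state$u_mot[i] + mp$d_reset
    }
  }
  I_res <- noise[seq_len(n)]
  for (j in seq_len(n)) {
    if (state$fired_res[j]) {
      for (q in seq_len(topology$fanout)) {
        tgt <- topology$targets[q, j]
        I_res[tgt] <- I_res[tgt] + topology$tweights[q, j]
      }
    }
  }
  I_mot <- noise[n + seq_len(m)]
  for (r in seq_along(topology$output_ids)) {
    if (state$fired_res[topology$output_ids[r]]) {
      for (k in seq_len(m)) I_mot[k] <- I_mot[k] + plastic_weights[r, k]
    }
  }
  for (i in seq_len(n)) {
    vi <- state$v_res[i]; ui <- state$u_res[i]
    for (half in 1:2) vi <- vi + 0.5 * (0.04 * vi^2 + 5 * vi + 140 - ui + I_res[i])
    ui <- ui + topology$a[i] * (topology$b[i] * vi - ui)
    state$v_res[i] <- vi; state$u_res[i] <- ui
  }
  for (i in seq_len(m)) {
    vi <- state$v_mot[i]; ui <- state$u_mot[i]
    for (half in 1:2) vi <- vi + 0.5 * (0.04 * vi^2 + 5 * vi + 140 - ui + I_mot[i])
    ui <- ui + mp$a * (mp$b * vi - ui)
    state$v_mot[i] <- vi; state$u_mot[i] <- ui
  }
  state$fired_res <- fired_res
  state$fired_mot <- fired_mot
  state$t_ms <- state$t_ms + 1L
  list(state = state, spikes_res = fired_res, spikes_mot = fired_mot)
}

# Naive O(n*w) moving average over fully contained windows, drop-last
# convention (1000 -> 900).
smooth_naive <- function(raster, w) {
  out <- numeric(length(raster) - w)
  for (t in seq_along(out)) out[t] <- mean(raster[t:(t + w - 1)])
  out
}

# A small topology used throughout the unit tests.
tiny_topology <- function(seed = 42) {
  build_network(seed, n_reservoir = 60, n_inhibitory = 12, n_output = 10,
                n_motor = 10, fanout = 8)
}

# Small run config for orchestration tests.
tiny_config <- function(seed = 7, n_trials = 4, ...) {
  run_config(seed = seed, n_trials = n_trials, n_motor = 20,
             n_reservoir = 100, n_inhibitory = 20, fanout = 10, ...)
}
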