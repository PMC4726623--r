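#' Izhikevich neuron parameter sets
#'
#' Standard two-variable Izhikevich parameters. Excitatory reservoir neurons
#' and all motor neurons are regular spiking (a = 0.02, b = 0.2, c = -65,
#' d_reset = 8); inhibitory reservoir neurons are fast spiking (a = 0.1,
#' b = 0.2, c = -65, d_reset = 2). The recovery increment is named `d_reset`
#' to avoid clashing with the dopamine concentration `d`.
#'
#' @param type `"regular"` (excitatory / motor) or `"fast"` (inhibitory).
#' @param heterogeneous If `TRUE`, returns a function of a uniform deviate
#'   that jitters `c` and `d_reset` in the classic way (c = -65 + 15 r^2,
#'   d_reset = 8 - 6 r^2 for excitatory neurons). Defaults to homogeneous
#'   parameters.
#' @return A list with fields `a`, `b`, `c`, `d_reset`.
#' @export
neuron_params <- function(type = c("regular", "fast"), heterogeneous = FALSE) {
  type <- match.arg(type)
  p <- if (type == "regular") {
    list(a = 0.02, b = 0.2, c = -65, d_reset = 8)
  } else {
    list(a = 0.1, b = 0.2, c = -65, d_reset = 2)
  }
  if (heterogeneous) {
    if (type == "regular") {
      return(function(r) list(a = 0.02, b = 0.2, c = -65 + 15 * r^2,
                              d_reset = 8 - 6 * r^2))
    }
    return(function(r) list(a = 0.1 - 0.08 * r, b = 0.2 + 0.05 * r,
                            c = -65, d_reset = 2))
  }
  p
}

#' Build the spiking-network topology
#'
#' Constructs the recurrent reservoir (80% excitatory, 20% inhibitory by
#' default) plus the agonist/antagonist motor pools. Every reservoir neuron
#' gets exactly `fanout` outgoing connections to other reservoir neurons;
#' inhibitory neurons may connect only to excitatory neurons. Excitatory
#' outgoing weights are drawn from U(0, 1) and inhibitory ones from U(-1, 0);
#' these reservoir weights are fixed for the lifetime of the network. A random
#' subset of `n_output` excitatory neurons is designated as output neurons
#' projecting (all-to-all, via the plastic weights held separately in the
#' plasticity state) to the motor pool, whose first half is agonist and second
#' half antagonist.
#'
#' @param seed Integer seed; identical seeds give identical topologies.
#' @param n_reservoir Reservoir size (default 1000).
#' @param n_inhibitory Number of inhibitory reservoir neurons (default 200).
#' @param n_output Number of output neurons (default `n_motor`).
#' @param n_motor Total motor neurons, split half agonist / half antagonist
#'   (default 200; must be even).
#' @param fanout Outgoing connections per reservoir neuron (default 100).
#' @param heterogeneous Jitter neuron parameters as in the classic cortical
#'   network recipe (default `FALSE`: homogeneous).
#' @return An object of class `babble_topology`.
#' @export
build_network <- function(seed, n_reservoir = 1000, n_inhibitory = 200,
                          n_output = 200, n_motor = n_output, fanout = 100,
                          heterogeneous = FALSE) {
  n_excitatory <- n_reservoir - n_inhibitory
  if (n_inhibitory >= n_reservoir)
    stop("configuration error: n_inhibitory must be < n_reservoir")
  if (fanout >= n_reservoir)
    stop("configuration error: fanout must be < n_reservoir")
  if (n_output > n_excitatory)
    stop("configuration error: n_output exceeds the number of excitatory neurons")
  if (n_motor %% 2 != 0)
    stop("configuration error: n_motor must be even")
  if (n_output != n_motor)
    stop("configuration error: n_output must equal n_motor (matched pools)")

  set.seed(seed)
  excitatory_ids <- seq_len(n_excitatory)
  inhibitory_ids <- seq.int(n_excitatory + 1L, n_reservoir)

  targets <- matrix(0L, nrow = fanout, ncol = n_reservoir)
  tweights <- matrix(0, nrow = fanout, ncol = n_reservoir)
  for (j in seq_len(n_reservoir)) {
    if (j <= n_excitatory) {
      pool <- setdiff(seq_len(n_reservoir), j)
      w <- stats::runif(fanout, 0, 1)
    } else {
      pool <- excitatory_ids
      w <- stats::runif(fanout, -1, 0)
    }
    targets[, j] <- sample(pool, fanout, replace = FALSE)
    tweights[, j] <- w
  }

  output_ids <- sort(sample(excitatory_ids, n_output, replace = FALSE))
  half <- n_motor %/% 2L

  rs <- neuron_params("regular")
  fs <- neuron_params("fast")
  a <- c(rep(rs$a, n_excitatory), rep(fs$a, n_inhibitory))
  b <- c(rep(rs$b, n_excitatory), rep(fs$b, n_inhibitory))
  cc <- c(rep(rs$c, n_excitatory), rep(fs$c, n_inhibitory))
  dr <- c(rep(rs$d_reset, n_excitatory), rep(fs$d_reset, n_inhibitory))
  if (heterogeneous) {
    re <- stats::runif(n_excitatory)
    ri <- stats::runif(n_inhibitory)
    cc[excitatory_ids] <- -65 + 15 * re^2
    dr[excitatory_ids] <- 8 - 6 * re^2
    a[inhibitory_ids] <- 0.02 + 0.08 * ri
    b[inhibitory_ids] <- 0.25 - 0.05 * ri
  }

  structure(list(
    n_reservoir = n_reservoir, n_inhibitory = n_inhibitory,
    n_excitatory = n_excitatory, n_output = n_output, n_motor = n_motor,
    fanout = fanout,
    excitatory_ids = excitatory_ids, inhibitory_ids = inhibitory_ids,
    output_ids = output_ids,
    agonist_ids = seq_len(half), antagonist_ids = seq.int(half + 1L, n_motor),
    targets = targets, tweights = tweights,
    a = a, b = b, c = cc, d_reset = dr,
    motor_params = neuron_params("regular"),
    seed = seed
  ), class = "babble_topology")
}

#' @export
print.babble_topology <- function(x, ...) {
  cat("<babble_topology>\n",
      " reservoir: ", x$n_reservoir, " neurons (", x$n_inhibitory,
      " inhibitory), fanout ", x$fanout, "\n",
      " output neurons: ", x$n_output, "; motor pool: ", x$n_motor,
      " (", length(x$agonist_ids), " agonist / ",
      length(x$antagonist_ids), " antagonist)\n", sep = "")
  invisible(x)
}

#' Dense reservoir weight matrix
#'
#' Expands the compact fanout representation into the full `n x n` matrix
#' `W[post, pre]`, mostly for the reference stepping implementation and for
#' serialization.
#'
#' @param topology A `babble_topology`.
#' @return A dense numeric matrix.
#' @export
reservoir_matrix <- function(topology) {
  n <- topology$n_reservoir
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    W[topology$targets[, j], j] <- topology$tweights[, j]
  }
  W
}

#' Per-neuron input noise
#'
#' Draws i.i.d. uniform input currents on \[-amplitude, amplitude\] pA,
#' the spontaneous drive given to every reservoir and motor neuron each ms.
#'
#' @param n Number of draws (>= 1).
#' @param amplitude Half-width of the uniform distribution (default 6.5 pA).
#' @param seed Optional seed; when given, the stream is reproducible
#'   independently of the caller's RNG state.
#' @return Numeric vector of length `n`.
#' @export
sample_noise <- function(n, amplitude = 6.5, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, -amplitude, amplitude)
}

#' Initialize membrane state
#'
#' All neurons start at rest: v = -65 mV, u = b * v, no spikes pending.
#'
#' @param topology A `babble_topology`.
#' @return A list holding reservoir and motor membrane variables, the spike
#'   flags from the previous ms, and the global ms counter.
#' @export
init_network_state <- function(topology) {
  n <- topology$n_reservoir
  m <- topology$n_motor
  mp <- topology$motor_params
  list(
    v_res = rep(-65, n), u_res = topology$b * (-65),
    fired_res = rep(FALSE, n),
    v_mot = rep(-65, m), u_mot = rep(mp$b * (-65), m),
    fired_mot = rep(FALSE, m),
    t_ms = 0L
  )
}

#' Step the network by one millisecond (reference implementation)
#'
#' Vectorized R implementation of the per-ms update. At step entry, neurons
#' with v >= 30 mV emit a spike for this ms and are reset (v <- c,
#' u <- u + d_reset). Input current is the noise draw plus the summed weights
#' from presynaptic neurons that spiked in the previous ms. Membrane potential
#' is then integrated in two half-ms sub-steps, followed by the recovery
#' update. Motor neurons receive input only from output-neuron spikes through
#' the plastic weights, plus noise.
#'
#' The compiled trial kernel used by [run_simulation()] applies exactly this
#' update; this function is the module surface and the oracle it is tested
#' against.
#'
#' @param state State list from [init_network_state()] or a previous step.
#' @param topology A `babble_topology`.
#' @param plastic_weights `n_output x n_motor` matrix of output-to-motor
#'   synapse strengths.
#' @param noise Numeric vector of length `n_reservoir + n_motor` (reservoir
#'   entries first).
#' @return List with the updated `state` and logical spike vectors
#'   `spikes_res`, `spikes_mot` for this ms.
#' @export
step_network <- function(state, topology, plastic_weights, noise) {
  n <- topology$n_reservoir
  m <- topology$n_motor
  stopifnot(length(noise) == n + m)

  fired_res <- state$v_res >= 30
  state$v_res[fired_res] <- topology$c[fired_res]
  state$u_res[fired_res] <- state$u_res[fired_res] + topology$d_reset[fired_res]
  fired_mot <- state$v_mot >= 30
  mp <- topology$motor_params
  state$v_mot[fired_mot] <- mp$c
  state$u_mot[fired_mot] <- state$u_mot[fired_mot] + mp$d_reset

  I_res <- noise[seq_len(n)]
  prev <- which(state$fired_res)
  for (j in prev) {
    tg <- topology$targets[, j]
    I_res[tg] <- I_res[tg] + topology$tweights[, j]
  }
  I_mot <- noise[n + seq_len(m)]
  prev_out <- state$fired_res[topology$output_ids]
  if (any(prev_out)) {
    I_mot <- I_mot + colSums(plastic_weights[prev_out, , drop = FALSE])
  }

  for (half in 1:2) {
    state$v_res <- state$v_res +
      0.5 * (0.04 * state$v_res^2 + 5 * state$v_res + 140 - state$u_res + I_res)
    state$v_mot <- state$v_mot +
      0.5 * (0.04 * state$v_mot^2 + 5 * state$v_mot + 140 - state$u_mot + I_mot)
  }
  state$u_res <- state$u_res + topology$a * (topology$b * state$v_res - state$u_res)
  state$u_mot <- state$u_mot + mp$a * (mp$b * state$v_mot - state$u_mot)

  if (any(!is.finite(state$v_res)) || any(!is.finite(state$u_res)) ||
      any(!is.finite(state$v_mot)) || any(!is.finite(state$u_mot)))
    stop("runtime integrity error: non-finite membrane state")

  state$fired_res <- fired_res
  state$fired_mot <- fired_mot
  state$t_ms <- state$t_ms + 1L
  list(state = state, spikes_res = fired_res, spikes_mot = fired_mot)
}

#' Serialize topology weights
#'
#' Writes the reservoir connectivity as a portable long-format CSV
#' (pre, post, weight), one row per edge.
#'
#' @param topology A `babble_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  n <- topology$n_reservoir
  df <- data.frame(
    pre = rep(seq_len(n), each = topology$fanout),
    post = as.vector(topology$targets),
    weight = as.vector(topology$tweights)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
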