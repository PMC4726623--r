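#' Plasticity parameters
#'
#' Constants of the dopamine-modulated, LTP-only STDP rule on the
#' output-to-motor synapses: the dopamine trace decays by 0.995 per ms, a
#' presynaptic spike sets the firing memory to 0.1 which decays by 0.95 per
#' ms, the eligibility trace decays by 0.99 per 10-ms update interval,
#' synapse strength is capped at 4, and each reward adds 1 to the dopamine
#' concentration. Weight updates (cap, then normalization, then eligibility
#' decay) happen on 10-ms boundaries of the global clock.
#'
#' @param da_decay Per-ms dopamine decay factor.
#' @param trace_bump Value assigned to the presynaptic trace on a spike.
#' @param trace_decay Per-ms presynaptic-trace decay factor.
#' @param elig_decay Per-update-interval eligibility decay factor.
#' @param weight_cap Maximum synapse strength.
#' @param da_bump Dopamine added per reward.
#' @param update_interval Milliseconds between weight updates.
#' @param normalize `"mean"` divides all weights by their mean after each
#'   update (the default); `"sum"` divides by the grand sum (kept switchable
#'   for sensitivity analysis; it collapses the weight scale).
#' @return A list of class `plasticity_params`.
#' @export
plasticity_params <- function(da_decay = 0.995, trace_bump = 0.1,
                              trace_decay = 0.95, elig_decay = 0.99,
                              weight_cap = 4, da_bump = 1,
                              update_interval = 10L,
                              normalize = c("mean", "sum")) {
  normalize <- match.arg(normalize)
  stopifnot(da_decay > 0, da_decay < 1, trace_decay > 0, trace_decay < 1,
            elig_decay > 0, elig_decay < 1, weight_cap > 0)
  structure(list(da_decay = da_decay, trace_bump = trace_bump,
                 trace_decay = trace_decay, elig_decay = elig_decay,
                 weight_cap = weight_cap, da_bump = da_bump,
                 update_interval = as.integer(update_interval),
                 normalize = normalize),
            class = "plasticity_params")
}

#' Initialize the plasticity state
#'
#' Dopamine, presynaptic traces, and eligibility traces start at zero; the
#' plastic output-to-motor weights are drawn elementwise from U(0, 1).
#'
#' @param topology A `babble_topology` (defines the matrix dimensions).
#' @param seed Optional seed for the weight draw.
#' @return List with fields `d` (dopamine), `c` (presynaptic trace per output
#'   neuron), `e` (eligibility per synapse), `s` (synapse strengths,
#'   `n_output x n_motor`).
#' @export
init_plasticity <- function(topology, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_out <- topology$n_output
  n_mot <- topology$n_motor
  list(
    d = 0,
    c = rep(0, n_out),
    e = matrix(0, n_out, n_mot),
    s = matrix(stats::runif(n_out * n_mot, 0, 1), n_out, n_mot)
  )
}

#' Per-millisecond plasticity update (reference implementation)
#'
#' Executes one ms of the reward-modulated STDP bookkeeping, in order:
#' dopamine decays; each motor spike adds the current presynaptic traces to
#' its incoming eligibility traces (traces are read before this ms's
#' presynaptic spikes are registered, so a same-ms pre/post pair does not
#' potentiate); each output spike sets its trace to `trace_bump`, then all
#' traces decay; on 10-ms boundaries of the global clock the weight update of
#' [apply_weight_update()] runs (cap, normalization, eligibility decay); if a
#' reward arrives this ms, dopamine is bumped last.
#'
#' @param state Plasticity state from [init_plasticity()].
#' @param output_spikes Logical vector over output neurons for this ms.
#' @param motor_spikes Logical vector over motor neurons for this ms.
#' @param t_ms Global millisecond index (weight updates fire when
#'   `t_ms %% update_interval == 0`).
#' @param params A `plasticity_params`.
#' @param reward If `TRUE`, a reward is delivered at the end of this ms.
#' @return The updated state.
#' @export
per_ms_update <- function(state, output_spikes, motor_spikes, t_ms,
                          params = plasticity_params(), reward = FALSE) {
  stopifnot(length(output_spikes) == nrow(state$s),
            length(motor_spikes) == ncol(state$s))
  state$d <- state$d * params$da_decay
  if (any(motor_spikes)) {
    state$e[, motor_spikes] <- state$e[, motor_spikes] + state$c
  }
  state$c[output_spikes] <- params$trace_bump
  state$c <- state$c * params$trace_decay
  if (t_ms %% params$update_interval == 0) {
    state <- apply_weight_update(state, params)
  }
  if (reward) state <- deliver_reward(state, params)
  state
}

#' Weight update on a 10-ms boundary
#'
#' Each synapse gains `e * d` (eligibility times dopamine), capped at
#' `weight_cap`; all weights are then normalized by dividing by their mean
#' (or grand sum, if so configured), and the eligibility traces decay by
#' `elig_decay`.
#'
#' @inheritParams per_ms_update
#' @return The updated state.
#' @export
apply_weight_update <- function(state, params = plasticity_params()) {
  s <- pmin(state$s + state$e * state$d, params$weight_cap)
  divisor <- if (params$normalize == "mean") mean(s) else sum(s)
  if (divisor == 0) stop("integrity error: weight matrix mean is zero")
  state$s <- s / divisor
  state$e <- state$e * params$elig_decay
  state
}

#' Deliver one reward
#'
#' Adds `da_bump` (1 by default) to the dopamine concentration. Nothing else
#' changes; the conversion of eligibility into weight change happens at the
#' following 10-ms updates while the dopamine transient decays.
#'
#' @inheritParams per_ms_update
#' @return The updated state.
#' @export
deliver_reward <- function(state, params = plasticity_params()) {
  state$d <- state$d + params$da_bump
  state
}

#' Brute-force eligibility oracle
#'
#' Computes the eligibility trace of a single synapse directly from its spike
#' times, independently of the incremental per-ms bookkeeping: each post
#' spike at t_q contributes `trace_bump * trace_decay^(t_q - t_p)` for the
#' most recent pre spike t_p < t_q (the presynaptic trace is set, not summed,
#' on a spike), and each contribution then decays
#' by `elig_decay` once per update boundary (multiple of `update_interval`)
#' in (t_q, query_ms\], boundaries at t_q itself included (the boundary update
#' runs after that ms's eligibility increment).
#'
#' @param pre_spike_times Sorted integer ms times of presynaptic (output
#'   neuron) spikes.
#' @param post_spike_times Sorted integer ms times of postsynaptic (motor
#'   neuron) spikes.
#' @param query_ms Time at which to evaluate (>= all spike times); the value
#'   returned is the trace at the end of that ms.
#' @param params A `plasticity_params`.
#' @return The eligibility value.
#' @export
eligibility_oracle <- function(pre_spike_times, post_spike_times, query_ms,
                               params = plasticity_params()) {
  if (is.unsorted(pre_spike_times) || is.unsorted(post_spike_times))
    stop("spike time lists must be sorted")
  if (length(c(pre_spike_times, post_spike_times)) &&
      query_ms < max(c(pre_spike_times, post_spike_times)))
    stop("query_ms must be >= all spike times")
  total <- 0
  for (tq in post_spike_times) {
    earlier <- pre_spike_times[pre_spike_times < tq]
    if (length(earlier) == 0) next
    # the trace is SET (not summed) on a presynaptic spike, so only the most
    # recent pre spike before the post spike contributes
    tp <- max(earlier)
    contrib <- params$trace_bump * params$trace_decay^(tq - tp)
    n_boundaries <- length(seq_boundaries(tq, query_ms,
                                          params$update_interval))
    total <- total + contrib * params$elig_decay^n_boundaries
  }
  total
}

# multiples of `interval` in [from, to]
seq_boundaries <- function(from, to, interval) {
  lo <- ceiling(from / interval)
  hi <- floor(to / interval)
  if (hi < lo) integer(0) else seq.int(lo, hi)
}
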