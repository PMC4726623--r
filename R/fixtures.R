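# Synthetic inputs with known structure, so that every stage of the pipeline
# is testable without external data. Each generator bundles its ground truth
# with the data it returns.

#' Waveform of k separated voiced bursts
#'
#' Builds a waveform containing `k` voiced (pulse-train) bursts with smooth
#' raised-cosine ramps, separated by silences. With the default 0.35-s gaps
#' the bursts satisfy every criterion of the syllable-nucleus detector, so
#' the expected count is exactly `k`.
#'
#' @param k Number of bursts (>= 0).
#' @param f0 Burst fundamental in Hz.
#' @param burst_dur_s Burst duration in s.
#' @param gap_s Silence between bursts in s.
#' @param fs Sampling rate in Hz.
#' @param duration_s Total duration; defaults to the smallest of 0.9 s or
#'   what the bursts require (plus padding).
#' @param ramp_s Raised-cosine ramp length at each burst edge.
#' @return List with `wave` (a `waveform`), `expected_nuclei = k`, and the
#'   burst onset times.
#' @export
make_burst_waveform <- function(k, f0 = 220, burst_dur_s = 0.12,
                                gap_s = 0.35, fs = 22050,
                                duration_s = NULL, ramp_s = 0.01) {
  stopifnot(k >= 0)
  span <- if (k > 0) k * burst_dur_s + (k - 1) * gap_s else 0
  pad <- 0.05
  if (is.null(duration_s)) duration_s <- max(0.9, span + 2 * pad)
  if (span + 2 * pad > duration_s + 1e-12)
    stop("infeasible packing: bursts do not fit in the requested duration")
  n <- round(duration_s * fs)
  x <- numeric(n)
  onsets <- if (k > 0) pad + (seq_len(k) - 1) * (burst_dur_s + gap_s)
    else numeric(0)
  nb <- round(burst_dur_s * fs)
  t_b <- (seq_len(nb) - 1) / fs
  period <- fs / f0
  pulse <- ifelse((seq_len(nb) - 1) %% period < 1, 1, 0)
  # decaying one-pole ring after each pulse gives a voiced, periodic burst
  src <- as.numeric(stats::filter(pulse, 0.95, method = "recursive"))
  env <- rep(1, nb)
  nr <- round(ramp_s * fs)
  if (nr > 0 && 2 * nr < nb) {
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
    env[seq_len(nr)] <- ramp
    env[seq.int(nb - nr + 1, nb)] <- rev(ramp)
  }
  burst <- src * env
  burst <- 0.8 * burst / max(abs(burst))
  for (on in onsets) {
    i0 <- round(on * fs) + 1
    x[i0:(i0 + nb - 1)] <- burst
  }
  list(wave = structure(x, sample_rate = fs, class = "waveform"),
       expected_nuclei = k, onsets = onsets, t = t_b)
}

#' Salience sequence with an oracle reward trajectory
#'
#' Returns a salience sequence together with the (r, theta) trajectory
#' produced by an independent, literal transcription of the adaptive
#' threshold rule (threshold 4.5, +0.1 when at least 3 of the last 10
#' trials were rewarded, history reset on increment). This is the oracle
#' against which the incremental [evaluate_trial()] state machine is tested.
#'
#' @param S Numeric vector of salience scores (the "pattern" of super- and
#'   sub-threshold trials).
#' @param init,increment,criterion Threshold rule constants.
#' @return List with `S` and data frame `oracle` (trial, r, theta_at_eval,
#'   theta_after).
#' @export
make_reward_sequence <- function(S, init = 4.5, increment = 0.1,
                                 criterion = 3) {
  theta <- init
  h <- rep(0, 10)
  rows <- vector("list", length(S))
  for (i in seq_along(S)) {
    r <- if (S[i] > theta) 1 else 0
    theta_at_eval <- theta
    h <- c(h[-1], r)
    if (sum(h) >= criterion) {
      theta <- theta + increment
      h <- rep(0, 10)
    }
    rows[[i]] <- data.frame(trial = i, r = r, theta_at_eval = theta_at_eval,
                            theta_after = theta)
  }
  list(S = S, oracle = do.call(rbind, rows))
}

#' Muscle series with closed-form statistics
#'
#' @param shape `"constant"`, `"sine"`, or `"step"`.
#' @param value Constant level (shape `"constant"`).
#' @param amplitude,periods Sine amplitude about 0 and whole number of
#'   periods (shape `"sine"`).
#' @param low,high Step levels, half the series each (shape `"step"`).
#' @param length_out Series length (default 900).
#' @return A `muscle_series` with attributes `true_mean` and `true_sd`
#'   (population SD).
#' @export
make_muscle_series <- function(shape = c("constant", "sine", "step"),
                               value = 0.2, amplitude = 0.3, periods = 3,
                               low = 0, high = 1, length_out = 900L) {
  shape <- match.arg(shape)
  n <- as.integer(length_out)
  if (shape == "constant") {
    x <- rep(value, n)
    tm <- value; ts <- 0
  } else if (shape == "sine") {
    x <- amplitude * sin(2 * pi * periods * (seq_len(n) - 1) / n)
    tm <- 0; ts <- amplitude / sqrt(2)
  } else {
    x <- c(rep(low, n %/% 2), rep(high, n - n %/% 2))
    tm <- (low + high) / 2; ts <- abs(high - low) / 2
  }
  structure(x, true_mean = tm, true_sd = ts, trial_index = NA_integer_,
            class = "muscle_series")
}

#' Muscle series with a known number of closure episodes
#'
#' Builds a 900-ms muscle series that exceeds the surrogate's rest aperture
#' during exactly `k` separated episodes, producing `k` closure (consonant)
#' events in the synthesized sound. Used to test the salience score's
#' monotonicity in syllabicity.
#'
#' @param k Number of closure episodes.
#' @param rest_aperture Aperture the episodes must exceed (default 0.5).
#' @param episode_ms Closure episode duration in ms.
#' @param base Muscle level outside episodes.
#' @return A `muscle_series` of length 900 with attribute `closures = k`.
#' @export
make_closure_series <- function(k, rest_aperture = 0.5, episode_ms = 80L,
                                base = 0.1) {
  stopifnot(k >= 0, k * episode_ms < 800)
  x <- rep(base, 900)
  if (k > 0) {
    # k (open, closure) pairs tile the 900 ms, each closure ending its pair,
    # so the sound contains exactly k voiced bursts and k closure events
    pair <- 900L %/% k
    for (i in seq_len(k)) {
      hi <- if (i == k) 900L else i * pair
      x[(hi - episode_ms + 1):hi] <- rest_aperture + 0.3
    }
  }
  structure(x, closures = k, trial_index = NA_integer_,
            class = "muscle_series")
}
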