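# Auditory salience surrogate: cochleagram (log-spaced filterbank energies at
# a 1-ms frame step) followed by per-band onset/offset transient detection.
# The trained cortical-filter stage of the full salience model is out of
# scope; the spectrotemporal-transient stage preserved here is what makes the
# score track consonant-vowel alternation (more closure/opening transitions,
# higher salience), which is the property the learning loop needs.

# Fixed output scale of the transient trace. Calibrated once so that
# untrained vocalizations of the reference condition (200 motor neurons,
# m = 2) score about 5 salience units, the operating point at which the
# adaptive reward threshold (initialized at 4.5) engages.
SALIENCE_SCALE <- 2.69e-4

#' Cochleagram of a waveform
#'
#' Short-time band energies on a log-spaced filterbank, one frame per ms.
#' Each frame is Hann-windowed, and bin powers are summed within each band
#' and log-compressed. Digital silence maps to a uniform floor.
#'
#' @param wave Waveform samples (numeric) or a `waveform` object.
#' @param sample_rate Hz; defaults to the waveform's attribute or 22050.
#' @param n_bands Number of log-spaced bands (default 32).
#' @param fmin,fmax Band range in Hz (defaults 100 and 8000).
#' @param window Analysis window length in samples (default 256).
#' @param floor_energy Additive energy floor before log compression.
#' @return A `n_bands x n_frames` matrix of log-energies (dB-like units),
#'   with attribute `frame_step_ms = 1`.
#' @export
cochleagram <- function(wave, sample_rate = NULL, n_bands = 32,
                        fmin = 100, fmax = 8000, window = 256,
                        floor_energy = 1e-10) {
  if (length(wave) == 0) stop("empty waveform")
  if (is.null(sample_rate))
    sample_rate <- attr(wave, "sample_rate") %||% 22050
  x <- as.numeric(wave)
  n_frames <- floor(length(x) / sample_rate * 1000)
  if (n_frames < 1) stop("waveform shorter than one frame")
  idx <- frame_index_matrix(length(x), sample_rate, window, n_frames)
  if (attr(idx, "pad") > 0) x <- c(x, numeric(attr(idx, "pad")))
  frames <- matrix(x[idx], nrow = window)
  han <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window) - 1) / (window - 1))
  spec <- stats::mvfft(frames * han)
  nb <- window %/% 2 + 1
  spec <- spec[seq_len(nb), , drop = FALSE]
  power <- Re(spec)^2 + Im(spec)^2
  freqs <- (seq_len(nb) - 1) * sample_rate / window
  edges <- exp(seq(log(fmin), log(fmax), length.out = n_bands + 1))
  band_of <- findInterval(freqs, edges, rightmost.closed = TRUE)
  keep <- band_of >= 1 & band_of <= n_bands
  agg <- matrix(0, n_bands, nb)                       # band aggregation map
  agg[cbind(band_of[keep], which(keep))] <- 1
  energy <- agg %*% power
  out <- 10 * log10(energy + floor_energy)
  attr(out, "frame_step_ms") <- 1
  out
}

# Frame-extraction index matrices are deterministic in (n, sr, window); cache
# the most recent one since every trial of a run analyzes same-length audio.
.coch_cache <- new.env(parent = emptyenv())

frame_index_matrix <- function(n, sample_rate, window, n_frames) {
  key <- paste(n, sample_rate, window, n_frames)
  hit <- .coch_cache$key
  if (identical(hit, key)) return(.coch_cache$idx)
  starts <- round((seq_len(n_frames) - 1) * sample_rate / 1000)
  idx <- outer(seq_len(window), starts, `+`)          # 1-based sample indices
  attr(idx, "pad") <- max(0L, max(idx) - n)
  .coch_cache$key <- key
  .coch_cache$idx <- idx
  idx
}

#' Spectrotemporal transient trace
#'
#' Per-band temporal edge detection: for each band, the mean log-energy over
#' the coming `delta_ms` frames minus the mean over the preceding `delta_ms`
#' frames, summed over bands and scaled. Positive values mark onsets, negative
#' values offsets; steady-state segments are near zero.
#'
#' @param coch Matrix from [cochleagram()].
#' @param delta_ms Half-width of the difference-of-causal-averages kernel
#'   (default 20 ms).
#' @param scale Output scale; the default places untrained reference-condition
#'   vocalization scores near the reward threshold's initial value.
#' @return Numeric per-ms salience trace (one value per cochleagram frame).
#' @export
transient_trace <- function(coch, delta_ms = 20, scale = SALIENCE_SCALE) {
  nt <- ncol(coch)
  d <- as.integer(delta_ms)
  # summing over bands commutes with the (band-independent) window means
  tot <- colSums(coch)
  cs <- c(0, cumsum(tot))
  t_idx <- seq_len(nt)
  blo <- pmax(1L, t_idx - d)
  bhi <- t_idx - 1L
  fhi <- pmin(nt, t_idx + d - 1L)
  back <- (cs[bhi + 1] - cs[blo]) / (bhi - blo + 1)
  fwd <- (cs[fhi + 1] - cs[t_idx]) / (fhi - t_idx + 1)
  trace <- fwd - back
  trace[bhi < blo] <- 0                              # no past context yet
  trace * scale
}

#' Total salience score
#'
#' Reduces a 900-ms salience trace to the scalar score: the sum of absolute
#' trace values from ms 151 through ms 900 (1-based), i.e. excluding the
#' first 150 ms, which carry the file-onset transient.
#'
#' @param trace Numeric salience trace of length 900.
#' @return Nonnegative scalar score.
#' @export
total_salience <- function(trace) {
  if (length(trace) != 900L) stop("salience trace must have length 900")
  sum(abs(trace[151:900]))
}

#' Salience score of a waveform
#'
#' Convenience wrapper: cochleagram, transient trace, then [total_salience()].
#'
#' @inheritParams cochleagram
#' @param ... Passed to [transient_trace()].
#' @return Scalar salience score.
#' @export
salience_score <- function(wave, sample_rate = NULL, ...) {
  total_salience(transient_trace(cochleagram(wave, sample_rate), ...))
}
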