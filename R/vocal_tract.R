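#' Surrogate synthesizer configuration
#'
#' Settings for the built-in one-degree-of-freedom articulatory surrogate and
#' for the exporter that emits scripts for the external articulatory
#' synthesizer. The fixed articulatory settings mirror the vocalization
#' recipe: adult female speaker, 22050 Hz, lung-volume targets 0.1 at 0 ms,
#' 0.1 at 20 ms, 0 at 50 ms and 0 at 900 ms, Interarytenoid 0.5 and
#' Hyoglossus 0.4 held throughout the 900-ms vocalization.
#'
#' @param sample_rate Audio sampling rate in Hz.
#' @param f0 Voicing fundamental in Hz (a generic adult-female value; the
#'   external synthesizer derives its own f0 from laryngeal physics).
#' @param rest_aperture Mouth aperture at zero net muscle activation, in
#'   (0, 1\]. The default 0.5 leaves the mouth half open at rest, so learned
#'   increases in mean activation move toward consonant-vowel alternation.
#' @param closure_threshold Aperture at or below which airflow is blocked.
#' @param lungs_schedule Two-column matrix of (time s, target lung volume).
#' @param interarytenoid,hyoglossus Fixed muscle settings exported to the
#'   external synthesizer.
#' @param envelope_exponent Exponent gamma applied to aperture when scaling
#'   output amplitude.
#' @param formant_map Length-2 vector: first-formant frequency (Hz) at full
#'   closure and at full opening.
#' @param bandwidth Resonance bandwidth in Hz.
#' @param exhale_tau Time constant (s) of the slow source-amplitude decay
#'   standing in for the emptying lungs.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(sample_rate = 22050, f0 = 220, rest_aperture = 0.5,
                         closure_threshold = 0,
                         lungs_schedule = cbind(time = c(0, 0.02, 0.05, 0.9),
                                                volume = c(0.1, 0.1, 0, 0)),
                         interarytenoid = 0.5, hyoglossus = 0.4,
                         envelope_exponent = 1,
                         formant_map = c(closed = 300, open = 1200),
                         bandwidth = 80, exhale_tau = 0.6) {
  stopifnot(sample_rate > 0, rest_aperture > 0, rest_aperture <= 1)
  structure(list(sample_rate = sample_rate, f0 = f0,
                 rest_aperture = rest_aperture,
                 closure_threshold = closure_threshold,
                 lungs_schedule = lungs_schedule,
                 interarytenoid = interarytenoid, hyoglossus = hyoglossus,
                 envelope_exponent = envelope_exponent,
                 formant_map = formant_map, bandwidth = bandwidth,
                 exhale_tau = exhale_tau),
            class = "synth_config")
}

#' Aperture trajectory from a muscle series
#'
#' Maps net masseter/orbicularis-oris activation to mouth aperture:
#' `aperture(t) = clamp(rest_aperture - muscle(t), 0, 1)`. Higher activation
#' closes the mouth; activation at or above `rest_aperture` produces full
#' closure (aperture 0), which blocks airflow in the surrogate.
#'
#' @param muscle Numeric muscle series (per-ms, length 900 for a standard
#'   trial).
#' @param config A `synth_config`.
#' @return Numeric aperture series of the same length, in \[0, 1\].
#' @export
aperture_trajectory <- function(muscle, config = synth_config()) {
  pmin(pmax(config$rest_aperture - as.numeric(muscle), 0), 1)
}

# Source-amplitude envelope standing in for lung emptying: the lung-volume
# schedule gates voicing on, a 10-ms onset ramp avoids a click, and a slow
# exponential decay sustains voicing over the 0.9 s as the air is expelled.
lungs_envelope <- function(n_samples, config) {
  fs <- config$sample_rate
  t <- (seq_len(n_samples) - 1) / fs
  sched <- config$lungs_schedule
  if (max(sched[, 2]) <= 0) return(rep(0, n_samples))
  ramp <- pmin(t / 0.01, 1)
  ramp * exp(-t / config$exhale_tau)
}

#' Synthesize a vocalization with the built-in surrogate
#'
#' A voiced source (pulse train at `f0`, amplitude following the lungs-driven
#' envelope) is passed through a time-varying single-resonance filter whose
#' center frequency follows the aperture,
#' `F1(t) = F1_closed + (F1_open - F1_closed) * aperture(t)`, and the result
#' is amplitude-scaled by `aperture(t)^gamma`. Full closure therefore yields
#' silence, and amplitude/formant transients appear exactly where the
#' aperture trajectory enters or leaves closure — the property the learning
#' loop exploits. Output is 0.9 s (19845 samples at 22050 Hz), peak-limited
#' to 1.
#'
#' @param muscle Muscle series of length 900 (per ms).
#' @param config A `synth_config`.
#' @return An object of class `waveform`: numeric samples with attribute
#'   `sample_rate`.
#' @export
synthesize_surrogate <- function(muscle, config = synth_config()) {
  stopifnot(length(muscle) == 900L)
  fs <- config$sample_rate
  n <- round(0.9 * fs)
  aperture_ms <- aperture_trajectory(muscle, config)
  ms_of_sample <- pmin(900L, floor((seq_len(n) - 1) / fs * 1000) + 1L)
  aperture <- aperture_ms[ms_of_sample]

  # impulse-train source at f0 via phase accumulator
  phase <- (seq_len(n) - 1) * config$f0 / fs
  src <- c(1, diff(floor(phase))) * 0.01
  src <- src * lungs_envelope(n, config)

  f1 <- config$formant_map[[1]] +
    (config$formant_map[[2]] - config$formant_map[[1]]) * aperture
  y <- resonator_cpp(src, f1, config$bandwidth, fs)

  gain <- aperture^config$envelope_exponent *
    (aperture > config$closure_threshold)
  y <- y * gain
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak
  structure(as.numeric(y), sample_rate = fs, class = "waveform")
}

#' Export a synthesis script for the external articulatory synthesizer
#'
#' Emits a plain-text script that drives the external articulatory
#' synthesizer with the exact per-trial settings: adult female speaker,
#' 0.9-s artword, lung-volume targets (0 s, 0.1), (0.02 s, 0.1), (0.05 s, 0),
#' (0.9 s, 0), Interarytenoid 0.5 and Hyoglossus 0.4 throughout, and per-ms
#' Masseter and OrbicularisOris targets both equal to the muscle series.
#' Output is byte-stable for identical inputs.
#'
#' @param muscle Muscle series of length 900.
#' @param config A `synth_config`.
#' @param path Optional file path; when given, the script is written there.
#' @param wav_out Name of the WAV file the script saves.
#' @return The script text as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
export_praat_script <- function(muscle, config = synth_config(), path = NULL,
                                wav_out = "vocalization.wav") {
  stopifnot(length(muscle) == 900L)
  num <- function(x) sprintf("%.6f", x)
  sched <- config$lungs_schedule
  lines <- c(
    "# Articulatory synthesis script (exported)",
    "Create Speaker... speaker Female 2",
    "Create Artword... vocalization 0.9",
    "select Artword vocalization",
    sprintf("Set target... %s %s Lungs", num(sched[, 1]), num(sched[, 2])),
    sprintf("Set target... %s %s Interarytenoid",
            num(c(0, 0.9)), num(config$interarytenoid)),
    sprintf("Set target... %s %s Hyoglossus",
            num(c(0, 0.9)), num(config$hyoglossus))
  )
  t_s <- (seq_len(900) - 1) / 1000
  v <- as.numeric(muscle)
  lines <- c(lines,
             sprintf("Set target... %s %s Masseter", num(t_s), num(v)),
             sprintf("Set target... %s %s OrbicularisOris", num(t_s), num(v)),
             "select Speaker speaker",
             "plus Artword vocalization",
             sprintf("To Sound... %d 25 0 0 0 0 0 0 0 0 0",
                     as.integer(config$sample_rate)),
             sprintf("Write to WAV file... %s", wav_out))
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    return(invisible(lines))
  }
  lines
}
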