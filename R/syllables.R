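#' Syllable-nucleus detector parameters
#'
#' Defaults follow the standard automatic nucleus counter for speech:
#' a silence threshold of -25 dB relative to the waveform's maximum
#' intensity, a minimum dip between peaks of 2 dB, and a minimum pause
#' duration of 0.3 s; voicing is checked by autocorrelation pitch detection
#' in 75-600 Hz.
#'
#' @param silence_threshold_db dB (re max intensity) below which frames count
#'   as silence.
#' @param min_dip_db Minimum intensity dip separating two nuclei.
#' @param min_pause_s Pauses at least this long split the sound into
#'   analysis chunks.
#' @param pitch_floor_hz,pitch_ceiling_hz Pitch search range.
#' @param frame_step_s,frame_window_s Intensity analysis frame step/window.
#' @param voicing_threshold Normalized autocorrelation peak required to call
#'   a frame voiced (steady pulse trains pass, white noise fails).
#' @return A list of class `nuclei_params`.
#' @export
nuclei_params <- function(silence_threshold_db = -25, min_dip_db = 2,
                          min_pause_s = 0.3, pitch_floor_hz = 75,
                          pitch_ceiling_hz = 600, frame_step_s = 0.01,
                          frame_window_s = 0.064, voicing_threshold = 0.45) {
  stopifnot(min_dip_db > 0, pitch_floor_hz < pitch_ceiling_hz)
  structure(list(silence_threshold_db = silence_threshold_db,
                 min_dip_db = min_dip_db, min_pause_s = min_pause_s,
                 pitch_floor_hz = pitch_floor_hz,
                 pitch_ceiling_hz = pitch_ceiling_hz,
                 frame_step_s = frame_step_s,
                 frame_window_s = frame_window_s,
                 voicing_threshold = voicing_threshold),
            class = "nuclei_params")
}

#' Framewise intensity contour
#'
#' RMS intensity per frame in dB relative to the loudest frame, floored at
#' -90 dB. All downstream thresholds are relative to this maximum, so nucleus
#' counts are invariant to global gain.
#'
#' @param wave Waveform samples or a `waveform`.
#' @param params A `nuclei_params`.
#' @param sample_rate Hz; defaults to the waveform's attribute or 22050.
#' @return Numeric dB series with attributes `frame_times` (s, frame centers)
#'   and `frame_starts` (1-based sample indices).
#' @export
intensity_contour <- function(wave, params = nuclei_params(),
                              sample_rate = NULL) {
  if (length(wave) == 0) stop("empty waveform")
  if (is.null(sample_rate))
    sample_rate <- attr(wave, "sample_rate") %||% 22050
  x <- as.numeric(wave)
  win <- round(params$frame_window_s * sample_rate)
  step <- params$frame_step_s * sample_rate
  if (length(x) < win) stop("waveform shorter than one analysis frame")
  n_frames <- floor((length(x) - win) / step) + 1
  starts <- round((seq_len(n_frames) - 1) * step) + 1
  rms <- vapply(starts, function(s0) {
    seg <- x[s0:(s0 + win - 1)]
    sqrt(mean(seg^2))
  }, numeric(1))
  ref <- max(rms)
  db <- if (ref > 0) 20 * log10(pmax(rms / ref, 1e-9)) else rep(-90, n_frames)
  db <- pmax(db, -90)
  attr(db, "frame_times") <- (starts - 1 + win / 2) / sample_rate
  attr(db, "frame_starts") <- starts
  attr(db, "sample_rate") <- sample_rate
  attr(db, "window") <- win
  db
}

# normalized autocorrelation voicing check at one frame
is_voiced_frame <- function(x, sample_rate, params) {
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom <= 0) return(FALSE)
  lag_min <- max(2L, floor(sample_rate / params$pitch_ceiling_hz))
  lag_max <- min(length(x) - 1L, ceiling(sample_rate / params$pitch_floor_hz))
  if (lag_max <= lag_min) return(FALSE)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = FALSE)$acf[-1]
  max(ac[lag_min:lag_max]) >= params$voicing_threshold
}

#' Count syllable nuclei
#'
#' Counts intensity peaks that (a) exceed the maximum intensity plus the
#' silence threshold (-25 dB), (b) are separated from neighboring accepted
#' peaks by dips of at least `min_dip_db`, and (c) are voiced at the peak
#' frame (autocorrelation pitch in the search range). Pauses of at least
#' `min_pause_s` below the silence threshold split the sound into chunks
#' that are peak-picked independently.
#'
#' @inheritParams intensity_contour
#' @param detail If `TRUE`, also return the per-peak table (time, intensity,
#'   voiced flag).
#' @return Integer nucleus count, or a list `(count, peaks)` when
#'   `detail = TRUE`.
#' @export
count_nuclei <- function(wave, params = nuclei_params(), sample_rate = NULL,
                         detail = FALSE) {
  db <- intensity_contour(wave, params, sample_rate)
  sample_rate <- attr(db, "sample_rate")
  n <- length(db)
  thr <- params$silence_threshold_db          # re max (max is 0 dB)
  speech <- db > thr

  # split into chunks at pauses >= min_pause_s
  min_pause_frames <- ceiling(params$min_pause_s / params$frame_step_s)
  chunks <- list()
  i <- 1
  while (i <= n) {
    if (!speech[i]) { i <- i + 1; next }
    j <- i
    gap <- 0
    last_speech <- i
    while (j < n && gap < min_pause_frames) {
      j <- j + 1
      if (speech[j]) { last_speech <- j; gap <- 0 } else gap <- gap + 1
    }
    chunks[[length(chunks) + 1]] <- c(i, last_speech)
    i <- last_speech + 1
  }

  x <- as.numeric(wave)
  win <- attr(db, "window")
  starts <- attr(db, "frame_starts")
  times <- attr(db, "frame_times")

  peak_rows <- list()
  for (ch in chunks) {
    lo <- ch[1]; hi <- ch[2]
    if (hi - lo < 1) seg_peaks <- if (speech[lo]) lo else integer(0)
    else {
      seg <- db[lo:hi]
      cand <- which(diff(sign(diff(c(-Inf, seg, -Inf)))) < 0)  # local maxima
      cand <- cand[seg[cand] > thr]
      seg_peaks <- integer(0)
      for (p in cand) {
        if (length(seg_peaks) == 0) { seg_peaks <- p; next }
        prev <- seg_peaks[length(seg_peaks)]
        valley <- min(seg[prev:p])
        if (min(seg[prev], seg[p]) - valley >= params$min_dip_db) {
          seg_peaks <- c(seg_peaks, p)
        } else if (seg[p] > seg[prev]) {
          seg_peaks[length(seg_peaks)] <- p   # merge: keep the louder peak
        }
      }
      seg_peaks <- seg_peaks + lo - 1
    }
    for (p in seg_peaks) {
      s0 <- starts[p]
      frame <- x[s0:min(length(x), s0 + win - 1)]
      voiced <- is_voiced_frame(frame, sample_rate, params)
      peak_rows[[length(peak_rows) + 1]] <-
        data.frame(time = times[p], intensity_db = db[p], voiced = voiced)
    }
  }
  peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
    data.frame(time = numeric(0), intensity_db = numeric(0),
               voiced = logical(0))
  count <- sum(peaks$voiced)
  if (detail) list(count = count, peaks = peaks) else count
}
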