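#' Motor-interface configuration
#'
#' @param window_ms Moving-average smoothing window (default 100 ms).
#' @param trial_ms Raster length per trial (default 1000 ms).
#' @param m Muscle scaling constant multiplying the net (agonist minus
#'   antagonist) smoothed activity (default 2; the sweep explores 2..8).
#' @return A list of class `motor_config`.
#' @export
motor_config <- function(window_ms = 100L, trial_ms = 1000L, m = 2) {
  stopifnot(window_ms < trial_ms, m > 0)
  structure(list(window_ms = as.integer(window_ms),
                 trial_ms = as.integer(trial_ms), m = m),
            class = "motor_config")
}

#' Moving-average smoothing of a pooled spike raster
#'
#' Applies a `window_ms` moving average to the per-ms pooled spike counts of
#' one motor pool. Only fully contained windows are used: output element `t`
#' (1-based) is the arithmetic mean of raster elements `t .. t + window_ms - 1`,
#' so a 1000-ms raster smoothed with a 100-ms window yields a 900-sample
#' series (mean pooled count per ms, not per neuron).
#'
#' @param raster Numeric vector of per-ms spike counts summed over the pool.
#' @param window_ms Window length in ms.
#' @return Numeric vector of length `length(raster) - window_ms`.
#' @export
smooth_spikes <- function(raster, window_ms = 100L) {
  n <- length(raster)
  w <- as.integer(window_ms)
  if (n < w) stop("raster shorter than the smoothing window")
  cs <- c(0, cumsum(raster))
  out_len <- n - w
  if (out_len == 0L) return((cs[n + 1] - cs[1]) / w)
  idx <- seq_len(out_len)
  (cs[idx + w] - cs[idx]) / w
}

#' Net muscle-activation series
#'
#' The smoothed antagonist series is subtracted from the smoothed agonist
#' series and the difference multiplied by the muscle scaling constant `m`.
#' Negative values correspond to antagonist dominance (mouth opening). The
#' same series drives both the masseter and the orbicularis oris.
#'
#' @param agonist_smoothed,antagonist_smoothed Smoothed series from
#'   [smooth_spikes()], equal length.
#' @param m Muscle scaling constant (> 0).
#' @param trial_index Optional trial index carried along for logging.
#' @return An object of class `muscle_series` (numeric vector with
#'   attributes).
#' @export
net_muscle <- function(agonist_smoothed, antagonist_smoothed, m = 2,
                       trial_index = NA_integer_) {
  if (length(agonist_smoothed) != length(antagonist_smoothed))
    stop("agonist and antagonist series lengths differ")
  stopifnot(m > 0)
  values <- m * (agonist_smoothed - antagonist_smoothed)
  structure(values, trial_index = trial_index, class = "muscle_series")
}
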