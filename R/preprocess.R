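#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth sections applied forward and backward
#' (`signal::filtfilt`), so the output has no phase lag: perievent timing
#' downstream is measured in milliseconds and must not be distorted by
#' filter latency.  The band is realized as a cascade of a high-pass and
#' a low-pass section, which stays numerically stable for bands that are
#' narrow relative to the sampling rate (e.g. 1-40 Hz at 2.5 kHz), where
#' a single transfer-function band-pass of the same order does not.
#' `low_hz = 0` degenerates to a pure low-pass.
#'
#' @param x a [continuous_signal()].
#' @param low_hz,high_hz band edges in Hz; `0 <= low < high < rate/2`.
#' @param order order of each section (default 4).
#' @return filtered `continuous_signal`, same length and rate.
#' @export
bandpass <- function(x, low_hz, high_hz, order = 4L) {
  stopifnot(inherits(x, "continuous_signal"))
  nyq <- x$rate_hz / 2
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("bandpass: need 0 <= low < high < rate/2 (= %g Hz)", nyq))
  y <- signal::filtfilt(signal::butter(order, high_hz / nyq, type = "low"),
                        x$samples)
  if (low_hz > 0)
    y <- signal::filtfilt(signal::butter(order, low_hz / nyq, type = "high"), y)
  if (!all(is.finite(y)))
    stop("bandpass: filter unstable for this band/rate combination")
  continuous_signal(y, x$rate_hz, x$t0_s, x$label, x$units)
}

# Internal: first-order exponential smoother, time constant tau_s.
ema_smooth <- function(v, rate_hz, tau_s) {
  a <- 1 - exp(-1 / (rate_hz * tau_s))
  as.numeric(stats::filter(a * v, 1 - a, method = "recursive", init = v[1L]))
}

#' Running RMS envelope
#'
#' Causal root-mean-square with exponential time constant `tau_s`
#' (default 0.01 s, the constant used for LFP spindle-band power and for
#' EMG envelopes throughout the pipeline): the squared signal is passed
#' through a first-order smoother and the square root taken.
#'
#' @param x a [continuous_signal()].
#' @param tau_s time constant in seconds (> 0).
#' @return nonnegative `continuous_signal`.
#' @export
rms_envelope <- function(x, tau_s = 0.01) {
  stopifnot(inherits(x, "continuous_signal"), tau_s > 0)
  y <- sqrt(pmax(ema_smooth(x$samples^2, x$rate_hz, tau_s), 0))
  continuous_signal(y, x$rate_hz, x$t0_s, paste0(x$label, "_rms"), x$units)
}

#' Rectify-and-smooth envelope
#'
#' Absolute value followed by the same first-order smoother as
#' [rms_envelope()].  Used for the forelimb EMG ahead of wake-movement
#' detection.
#'
#' @inheritParams rms_envelope
#' @return nonnegative `continuous_signal`.
#' @export
rectify_smooth <- function(x, tau_s = 0.01) {
  stopifnot(inherits(x, "continuous_signal"), tau_s > 0)
  y <- ema_smooth(abs(x$samples), x$rate_hz, tau_s)
  continuous_signal(y, x$rate_hz, x$t0_s, paste0(x$label, "_env"), x$units)
}

#' Threshold-crossing spike extraction from an MUA-band signal
#'
#' Plumbing stand-in for offline spike sorting: upward crossings of
#' `k_sd` robust standard deviations (median absolute deviation, so the
#' spikes themselves do not inflate the threshold) of the absolute
#' signal, with a refractory period.  A flat signal yields an empty
#' train, not an error.
#'
#' @param x MUA-band filtered [continuous_signal()].
#' @param k_sd threshold in robust SD units (default 4).
#' @param refractory_s minimum inter-event time, seconds (default 1 ms).
#' @return an [event_series()] of spike times (crossing times).
#' @export
extract_spikes <- function(x, k_sd = 4, refractory_s = 0.001) {
  stopifnot(inherits(x, "continuous_signal"), k_sd > 0)
  v <- abs(x$samples)
  s <- stats::mad(x$samples, center = stats::median(x$samples))
  if (s == 0) s <- stats::sd(x$samples)   # sparse spikes on a silent baseline
  if (s == 0) {
    return(event_series(numeric(), label = "spikes",
                        t0_s = x$t0_s, duration_s = signal_duration(x)))
  }
  th <- k_sd * s
  above <- v > th
  cross <- which(above & !c(FALSE, above[-length(above)]))
  tt <- x$t0_s + (cross - 1) / x$rate_hz
  if (length(tt) > 1L) {
    keep <- logical(length(tt)); keep[1L] <- TRUE; last <- tt[1L]
    for (i in 2L:length(tt)) {
      if (tt[i] - last >= refractory_s) { keep[i] <- TRUE; last <- tt[i] }
    }
    tt <- tt[keep]
  }
  event_series(tt, label = "spikes", t0_s = x$t0_s, duration_s = signal_duration(x))
}
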