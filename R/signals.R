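#' Uniformly sampled continuous signal
#'
#' Container for a single recording channel (EMG envelope, LFP, MUA band,
#' ...): a numeric sample vector plus sampling rate, start time, label and
#' units.  All downstream operations (filtering, envelopes, detectors,
#' waveform averages) consume and return this class.
#'
#' @param samples numeric vector of samples; must be finite and non-empty.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param t0_s time of the first sample, seconds.
#' @param label channel label.
#' @param units physical units of the samples.
#' @return an object of class `continuous_signal`.
#' @export
continuous_signal <- function(samples, rate_hz, t0_s = 0, label = "", units = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("continuous_signal: 'samples' must be non-empty")
  if (!all(is.finite(samples))) stop("continuous_signal: all samples must be finite")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) || rate_hz <= 0)
    stop("continuous_signal: 'rate_hz' must be a positive number")
  structure(list(samples = samples, rate_hz = as.numeric(rate_hz),
                 t0_s = as.numeric(t0_s),
                 label = as.character(label), units = as.character(units)),
            class = "continuous_signal")
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("<continuous_signal> %s: %d samples @ %g Hz (%.3f s), t0 = %g s%s\n",
              if (nzchar(x$label)) x$label else "unlabeled",
              length(x$samples), x$rate_hz, signal_duration(x), x$t0_s,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Sample times of a continuous signal
#' @param x a `continuous_signal`.
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "continuous_signal"))
  x$t0_s + (seq_along(x$samples) - 1) / x$rate_hz
}

#' Duration of a continuous signal in seconds
#' @param x a `continuous_signal`.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "continuous_signal"))
  length(x$samples) / x$rate_hz
}

#' @export
plot.continuous_signal <- function(x, ...) {
  graphics::plot(signal_times(x), x$samples, type = "l",
                 xlab = "time (s)",
                 ylab = if (nzchar(x$units)) x$units else "amplitude",
                 main = x$label, ...)
  invisible(x)
}

#' Sorted point-event series
#'
#' Times of point events (spikes, twitches, stimulations) in seconds,
#' optionally carrying the span of the recording they came from (used to
#' drop perievent windows that fall off the record edges).
#'
#' @param times_s numeric vector of event times, seconds; sorted
#'   non-decreasing (unsorted input is an error, not silently fixed).
#' @param label series label.
#' @param t0_s,duration_s optional recording span metadata.
#' @return an object of class `event_series`.
#' @export
event_series <- function(times_s, label = "", t0_s = NA_real_, duration_s = NA_real_) {
  times_s <- as.numeric(times_s)
  if (anyNA(times_s) || (length(times_s) && !all(is.finite(times_s))))
    stop("event_series: times must be finite")
  if (is.unsorted(times_s)) stop("event_series: times must be sorted non-decreasing")
  if (!is.na(t0_s) && !is.na(duration_s) && length(times_s)) {
    if (times_s[1L] < t0_s || times_s[length(times_s)] > t0_s + duration_s)
      stop("event_series: times outside the stated recording span")
  }
  structure(list(times_s = times_s, label = as.character(label),
                 t0_s = t0_s, duration_s = duration_s),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s: %d events%s\n",
              if (nzchar(x$label)) x$label else "unlabeled", length(x$times_s),
              if (length(x$times_s))
                sprintf(" in [%.3f, %.3f] s", min(x$times_s), max(x$times_s)) else ""))
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times_s)

#' Labeled half-open interval series
#'
#' Non-overlapping, sorted intervals `[onset, offset)` with one label per
#' interval (wake movements, sleep/wake bouts, spindle bursts).
#'
#' @param onset_s,offset_s interval bounds in seconds; `offset > onset`.
#' @param labels character vector (recycled if length 1).
#' @return an object of class `interval_series` (a data.frame with columns
#'   `onset_s`, `offset_s`, `label`).
#' @export
interval_series <- function(onset_s = numeric(), offset_s = numeric(), labels = character()) {
  onset_s <- as.numeric(onset_s); offset_s <- as.numeric(offset_s)
  if (length(onset_s) != length(offset_s))
    stop("interval_series: onset/offset length mismatch")
  if (length(labels) <= 1L) labels <- rep(if (length(labels)) labels else "", length(onset_s))
  if (length(labels) != length(onset_s))
    stop("interval_series: labels length mismatch")
  if (length(onset_s)) {
    if (any(offset_s <= onset_s)) stop("interval_series: intervals must have offset > onset")
    if (is.unsorted(onset_s)) stop("interval_series: intervals must be sorted by onset")
    if (any(onset_s[-1L] < offset_s[-length(offset_s)]))
      stop("interval_series: intervals must not overlap")
  }
  structure(data.frame(onset_s = onset_s, offset_s = offset_s,
                       label = as.character(labels), stringsAsFactors = FALSE),
            class = c("interval_series", "data.frame"))
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> %d intervals\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Durations of the intervals in a series, seconds
#' @param x an `interval_series`.
#' @export
interval_durations <- function(x) x$offset_s - x$onset_s

#' Which interval contains each time point
#'
#' Half-open convention: time `t` is inside interval `i` iff
#' `onset_s[i] <= t < offset_s[i]`.
#'
#' @param x an `interval_series`.
#' @param times_s numeric vector of query times.
#' @return integer vector of interval indices (`NA` where no interval
#'   contains the time).
#' @export
interval_index <- function(x, times_s) {
  if (!nrow(x)) return(rep(NA_integer_, length(times_s)))
  i <- findInterval(times_s, x$onset_s)
  inside <- i >= 1L & times_s < x$offset_s[pmax(i, 1L)]
  ifelse(inside, i, NA_integer_)
}

#' Label of the interval containing each time point
#' @inheritParams interval_index
#' @return character vector (`NA` outside all intervals).
#' @export
interval_label_at <- function(x, times_s) {
  i <- interval_index(x, times_s)
  ifelse(is.na(i), NA_character_, x$label[i])
}

# Internal: restrict an event vector to times inside intervals with a label.
events_in_state <- function(times_s, bouts, state) {
  lab <- interval_label_at(bouts, times_s)
  times_s[!is.na(lab) & lab == state]
}

#' Wake / active-sleep bout segmentation
#'
#' An `interval_series` whose labels are `"wake"` or `"active_sleep"` and
#' whose intervals exactly partition the recording span (contiguous, no
#' gaps, no overlap).
#'
#' @param onset_s,offset_s,labels as in [interval_series()].
#' @return object of class `c("bout_segmentation", "interval_series",
#'   "data.frame")`.
#' @export
bout_segmentation <- function(onset_s, offset_s, labels) {
  x <- interval_series(onset_s, offset_s, labels)
  if (!all(x$label %in% c("wake", "active_sleep")))
    stop("bout_segmentation: labels must be 'wake' or 'active_sleep'")
  if (nrow(x) > 1L && any(abs(x$onset_s[-1L] - x$offset_s[-nrow(x)]) > 1e-9))
    stop("bout_segmentation: bouts must tile the recording without gaps")
  class(x) <- c("bout_segmentation", class(x))
  x
}
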