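# Spindle-burst detection in the LFP by RMS thresholding.

#' Spindle detection criteria
#'
#' A spindle burst must comprise at least `min_oscillations`
#' oscillations, have a dominant frequency inside `freq_band_hz`
#' (10-15 Hz) and last at least `min_dur_s` (100 ms).  Detection runs on
#' the `lfp_band_hz` (1-40 Hz) band-passed signal via an RMS envelope
#' with time constant `rms_tau_s`.
#'
#' @param min_oscillations minimum oscillation count (default 3).
#' @param freq_band_hz dominant-frequency acceptance band, Hz.
#' @param min_dur_s minimum burst duration, seconds (default 0.1).
#' @param lfp_band_hz band-pass applied before detection, Hz.
#' @param rms_tau_s RMS time constant, seconds (default 0.01).
#' @param n_reference_bursts reference bursts averaged for the threshold
#'   (default 5).
#' @param merge_gap_s adjacent suprathreshold excursions closer than this
#'   are merged (default 0.05).
#' @param candidate_k candidate excursions are envelope runs above
#'   `candidate_k` times the median envelope (default 2).
#' @return list of class `spindle_criteria`.
#' @export
spindle_criteria <- function(min_oscillations = 3L,
                             freq_band_hz = c(10, 15),
                             min_dur_s = 0.1,
                             lfp_band_hz = c(1, 40),
                             rms_tau_s = 0.01,
                             n_reference_bursts = 5L,
                             merge_gap_s = 0.05,
                             candidate_k = 2) {
  if (min_dur_s <= 0) stop("spindle_criteria: 'min_dur_s' must be > 0")
  for (b in list(freq_band_hz, lfp_band_hz))
    if (length(b) != 2L || b[1L] >= b[2L])
      stop("spindle_criteria: frequency bands must satisfy low < high")
  structure(list(min_oscillations = as.integer(min_oscillations),
                 freq_band_hz = freq_band_hz, min_dur_s = min_dur_s,
                 lfp_band_hz = lfp_band_hz, rms_tau_s = rms_tau_s,
                 n_reference_bursts = as.integer(n_reference_bursts),
                 merge_gap_s = merge_gap_s, candidate_k = candidate_k),
            class = "spindle_criteria")
}

# Internal: candidate suprabaseline excursions of an envelope
# (runs above candidate_k x median), merged across short gaps.
candidate_excursions <- function(env, criteria) {
  v <- env$samples
  th0 <- criteria$candidate_k * stats::median(v)
  runs <- logical_runs(v > th0)
  merge_runs(runs, round(criteria$merge_gap_s * env$rate_hz))
}

# Internal: merge runs separated by fewer than gap samples.
merge_runs <- function(runs, gap) {
  if (nrow(runs) < 2L) return(runs)
  keep_start <- runs$start[1L]; out_s <- integer(); out_e <- integer()
  cur_e <- runs$end[1L]
  for (i in 2L:nrow(runs)) {
    if (runs$start[i] - cur_e < gap) cur_e <- runs$end[i]
    else { out_s <- c(out_s, keep_start); out_e <- c(out_e, cur_e)
           keep_start <- runs$start[i]; cur_e <- runs$end[i] }
  }
  data.frame(start = c(out_s, keep_start), end = c(out_e, cur_e))
}

#' Spindle-burst detection threshold
#'
#' The midpoint between the baseline RMS (median envelope outside
#' candidate excursions) and the mean peak RMS of the
#' `n_reference_bursts` largest candidate excursions.
#'
#' @param rms_env RMS envelope of the band-passed LFP
#'   ([continuous_signal()]).
#' @param criteria a [spindle_criteria()].
#' @return threshold value (same units as the envelope).
#' @export
spindle_threshold <- function(rms_env, criteria = spindle_criteria()) {
  stopifnot(inherits(rms_env, "continuous_signal"))
  runs <- candidate_excursions(rms_env, criteria)
  if (nrow(runs) < criteria$n_reference_bursts)
    stop(sprintf(
      "spindle_threshold: detection infeasible: %d candidate bursts (%d required)",
      nrow(runs), criteria$n_reference_bursts))
  v <- rms_env$samples
  outside <- rep(TRUE, length(v))
  for (i in seq_len(nrow(runs))) outside[runs$start[i]:(runs$end[i] - 1L)] <- FALSE
  baseline <- stats::median(v[outside])
  peaks <- vapply(seq_len(nrow(runs)),
                  function(i) max(v[runs$start[i]:(runs$end[i] - 1L)]), numeric(1))
  ref <- mean(sort(peaks, decreasing = TRUE)[seq_len(criteria$n_reference_bursts)])
  (baseline + ref) / 2
}

#' Dominant frequency of a signal segment
#'
#' Location of the periodogram peak (Hann window, zero-padded to at
#' least 1 Hz resolution) within a frequency band.
#'
#' @param segment a [continuous_signal()].
#' @param band_hz search band, Hz.
#' @param min_cycles minimum number of cycles of the band's low edge the
#'   segment must contain (default 2); shorter segments raise an
#'   undefined-frequency error.  Internal callers that enforce their own
#'   duration criterion may pass 0.
#' @return peak frequency in Hz.
#' @export
dominant_frequency <- function(segment, band_hz = c(1, 40), min_cycles = 2) {
  stopifnot(inherits(segment, "continuous_signal"))
  n <- length(segment$samples)
  dur <- n / segment$rate_hz
  if (min_cycles > 0 && dur * band_hz[1L] < min_cycles)
    stop(sprintf(
      "dominant_frequency: undefined: segment holds %.2f cycles at %g Hz (%g required)",
      dur * band_hz[1L], band_hz[1L], min_cycles))
  v <- segment$samples - mean(segment$samples)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / max(n - 1, 1)))  # Hann
  nfft <- 2^ceiling(log2(max(n, segment$rate_hz)))               # >= 1 Hz bins
  p <- Mod(stats::fft(c(v * w, numeric(nfft - n))))^2
  freq <- (seq_len(nfft) - 1) * segment$rate_hz / nfft
  sel <- which(freq >= band_hz[1L] & freq <= band_hz[2L])
  freq[sel[which.max(p[sel])]]
}

# Internal: oscillation count = zero-crossing pairs of the (mean-removed)
# band-filtered segment.
oscillation_count <- function(samples) {
  v <- samples - mean(samples)
  s <- sign(v); s <- s[s != 0]
  floor(sum(diff(s) != 0) / 2)
}

#' Detect spindle bursts in an LFP channel
#'
#' Band-passes the LFP (1-40 Hz), computes the RMS envelope (tau =
#' 0.01 s), thresholds it at the [spindle_threshold()] midpoint, merges
#' excursions separated by less than 50 ms, and accepts a burst iff its
#' duration is at least `min_dur_s`, its [dominant_frequency()] lies in
#' `freq_band_hz`, and it contains at least `min_oscillations`
#' oscillations (zero-crossing pairs).
#'
#' @param lfp raw or band-passed [continuous_signal()].
#' @param criteria a [spindle_criteria()].
#' @param prefiltered set `TRUE` when `lfp` is already band-passed.
#' @return data.frame of class `spindle_bursts` with columns `onset_s`,
#'   `offset_s`, `dominant_freq_hz`, `n_oscillations`, `peak_rms`; zero
#'   rows when nothing qualifies.
#' @export
detect_spindles <- function(lfp, criteria = spindle_criteria(), prefiltered = FALSE) {
  stopifnot(inherits(lfp, "continuous_signal"))
  filt <- if (prefiltered) lfp
          else bandpass(lfp, criteria$lfp_band_hz[1L], criteria$lfp_band_hz[2L])
  env <- rms_envelope(filt, criteria$rms_tau_s)
  empty <- structure(data.frame(onset_s = numeric(), offset_s = numeric(),
                                dominant_freq_hz = numeric(),
                                n_oscillations = integer(), peak_rms = numeric()),
                     class = c("spindle_bursts", "data.frame"))
  th <- tryCatch(spindle_threshold(env, criteria), error = function(e) NA_real_)
  if (is.na(th)) return(empty)
  runs <- merge_runs(logical_runs(env$samples > th),
                     round(criteria$merge_gap_s * env$rate_hz))
  if (!nrow(runs)) return(empty)
  rate <- env$rate_hz; tt <- signal_times(env)
  rows <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:(runs$end[i] - 1L)
    dur <- length(idx) / rate
    if (dur < criteria$min_dur_s) return(NULL)
    seg <- continuous_signal(filt$samples[idx], rate)
    f <- dominant_frequency(seg, band_hz = criteria$lfp_band_hz, min_cycles = 0)
    nosc <- oscillation_count(seg$samples)
    if (f < criteria$freq_band_hz[1L] || f > criteria$freq_band_hz[2L]) return(NULL)
    if (nosc < criteria$min_oscillations) return(NULL)
    data.frame(onset_s = tt[idx[1L]], offset_s = tt[idx[length(idx)]] + 1 / rate,
               dominant_freq_hz = f, n_oscillations = nosc,
               peak_rms = max(env$samples[idx]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("spindle_bursts", "data.frame")
  out
}
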