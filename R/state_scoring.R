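# Sleep-wake scoring and motor-event extraction from EMG envelopes.

#' Scoring configuration
#'
#' Parameters of the behavioral-state and motor-event detectors.
#' `twitch_k` is the twitch amplitude criterion in multiples of the
#' atonia baseline (strictly greater than); `wake_move_min_dur_s` is the
#' minimum suprathreshold duration of a wake movement.
#'
#' @param twitch_k twitch threshold multiplier (> 1; default 3).
#' @param wake_move_min_dur_s minimum movement duration, seconds
#'   (default 0.3).
#' @param min_bout_s minimum bout duration; shorter runs are merged into
#'   their neighbors (default 5).
#' @param tone_threshold_method `"midpoint"` (midpoint of a two-component
#'   split of the envelope distribution) or `"quantile"` (midpoint of the
#'   10th and 90th percentiles).
#' @param n_reference_movements number of largest candidate movements
#'   averaged for the movement threshold (default 5).
#' @param twitch_refractory_s minimum separation of twitch events
#'   (default 0.1).
#' @param twitch_time `"peak"` (default) or `"onset"`: which instant of a
#'   suprathreshold excursion is reported as the twitch time.
#' @return list of class `scoring_config`.
#' @export
scoring_config <- function(twitch_k = 3,
                           wake_move_min_dur_s = 0.3,
                           min_bout_s = 5,
                           tone_threshold_method = c("midpoint", "quantile"),
                           n_reference_movements = 5L,
                           twitch_refractory_s = 0.1,
                           twitch_time = c("peak", "onset")) {
  if (!is.numeric(twitch_k) || twitch_k <= 1) stop("scoring_config: 'twitch_k' must be > 1")
  if (wake_move_min_dur_s <= 0) stop("scoring_config: 'wake_move_min_dur_s' must be > 0")
  if (min_bout_s < 0) stop("scoring_config: 'min_bout_s' must be >= 0")
  structure(list(twitch_k = twitch_k,
                 wake_move_min_dur_s = wake_move_min_dur_s,
                 min_bout_s = min_bout_s,
                 tone_threshold_method = match.arg(tone_threshold_method),
                 n_reference_movements = as.integer(n_reference_movements),
                 twitch_refractory_s = twitch_refractory_s,
                 twitch_time = match.arg(twitch_time)),
            class = "scoring_config")
}

# Internal: runs of a logical vector as [onset, offset) sample intervals.
logical_runs <- function(b) {
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values] + 1L)  # half-open
}

#' Dichotomize nuchal EMG tone into wake and active-sleep bouts
#'
#' The envelope is thresholded at the midpoint between the two modes of
#' its amplitude distribution (2-means split; quantile fallback), samples
#' above threshold are labeled wake (high tone) and below atonia, and
#' runs shorter than `min_bout_s` are absorbed into their neighbors.  A
#' flat (unimodal, near-degenerate) envelope yields a single wake bout
#' with a warning.
#'
#' @param nuchal_env nonnegative [continuous_signal()] envelope of the
#'   nuchal EMG.
#' @param cfg a [scoring_config()].
#' @return a [bout_segmentation()] covering the recording.
#' @export
score_tone <- function(nuchal_env, cfg = scoring_config()) {
  stopifnot(inherits(nuchal_env, "continuous_signal"))
  v <- nuchal_env$samples
  rate <- nuchal_env$rate_hz
  t0 <- nuchal_env$t0_s
  dur <- signal_duration(nuchal_env)
  degenerate <- function() {
    warning("score_tone: degenerate (flat) envelope; returning a single wake bout")
    bout_segmentation(t0, t0 + dur, "wake")
  }
  rng <- range(v)
  if (diff(rng) < 1e-9 * max(abs(rng), 1)) return(degenerate())
  th <- if (cfg$tone_threshold_method == "midpoint") {
    km <- tryCatch(
      stats::kmeans(v, centers = range(v)),
      error = function(e) NULL)
    if (is.null(km)) return(degenerate())
    cen <- sort(km$centers[, 1L])
    if (cen[2L] / max(cen[1L], 1e-12) < 1.2) return(degenerate())
    mean(cen)
  } else {
    mean(stats::quantile(v, c(0.1, 0.9)))
  }
  wake <- v > th
  # merge runs shorter than min_bout_s into their neighbors, shortest first
  min_len <- round(cfg$min_bout_s * rate)
  r <- rle(wake)
  while (length(r$lengths) > 1L && any(r$lengths < min_len)) {
    i <- which.min(r$lengths)
    r$values[i] <- !r$values[i]
    r <- rle(inverse.rle(r))
  }
  wake <- inverse.rle(r)
  r <- rle(wake)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  bout_segmentation(t0 + starts / rate,
                    t0 + ifelse(ends == length(v), dur * rate, ends) / rate,
                    ifelse(r$values, "wake", "active_sleep"))
}

# Internal: median envelope over atonia (active-sleep) samples.
atonia_baseline <- function(env, bouts) {
  tt <- signal_times(env)
  lab <- interval_label_at(bouts, tt)
  v <- env$samples[!is.na(lab) & lab == "active_sleep"]
  if (!length(v)) return(NA_real_)
  stats::median(v)
}

#' Detect myoclonic twitches in a limb-EMG envelope
#'
#' A twitch is a suprathreshold excursion of the envelope strictly above
#' `twitch_k` times the atonia baseline (median envelope over
#' active-sleep samples) whose peak falls inside an active-sleep bout.
#' One event is reported per excursion, timed at the excursion peak
#' (configurable to onset), with a 100 ms refractory period.
#'
#' @param limb_env [continuous_signal()] limb-EMG envelope.
#' @param bouts a [bout_segmentation()] from [score_tone()].
#' @param cfg a [scoring_config()].
#' @return an [event_series()] of twitch times; empty when there are no
#'   active-sleep bouts.
#' @export
detect_twitches <- function(limb_env, bouts, cfg = scoring_config()) {
  stopifnot(inherits(limb_env, "continuous_signal"))
  dur <- signal_duration(limb_env)
  empty <- event_series(numeric(), "twitches", t0_s = limb_env$t0_s, duration_s = dur)
  base <- atonia_baseline(limb_env, bouts)
  if (is.na(base)) return(empty)
  th <- cfg$twitch_k * base
  v <- limb_env$samples
  runs <- logical_runs(v > th)          # strict '>' at k x baseline
  if (!nrow(runs)) return(empty)
  tt <- signal_times(limb_env)
  times <- vapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:(runs$end[i] - 1L)
    if (cfg$twitch_time == "peak") tt[idx[which.max(v[idx])]] else tt[idx[1L]]
  }, numeric(1))
  lab <- interval_label_at(bouts, times)
  times <- times[!is.na(lab) & lab == "active_sleep"]
  if (length(times) > 1L) {
    keep <- logical(length(times)); keep[1L] <- TRUE; last <- times[1L]
    for (i in 2L:length(times))
      if (times[i] - last >= cfg$twitch_refractory_s) { keep[i] <- TRUE; last <- times[i] }
    times <- times[keep]
  }
  event_series(times, "twitches", t0_s = limb_env$t0_s, duration_s = dur)
}

#' Detect wake movements in a limb-EMG envelope
#'
#' Candidate movements are suprathreshold excursions (above the twitch
#' threshold) that start inside a wake bout and last at least
#' `wake_move_min_dur_s`.  The maximum amplitudes of the
#' `n_reference_movements` largest candidates are averaged, and the final
#' threshold is the midpoint between the atonia baseline and that
#' average; movements are then the excursions above this midpoint
#' threshold, onset at the first crossing, that start in wake and last at
#' least `wake_move_min_dur_s`.  With fewer than `n_reference_movements`
#' (but at least one) candidates the available ones are used with a
#' warning; with none, the twitch threshold is used with a warning.
#'
#' @inheritParams detect_twitches
#' @return an [interval_series()] of movements.
#' @export
detect_wake_movements <- function(limb_env, bouts, cfg = scoring_config()) {
  stopifnot(inherits(limb_env, "continuous_signal"))
  base <- atonia_baseline(limb_env, bouts)
  if (is.na(base)) {
    warning("detect_wake_movements: no active-sleep samples; using envelope median as baseline")
    base <- stats::median(limb_env$samples)
  }
  tw_th <- cfg$twitch_k * base
  v <- limb_env$samples
  tt <- signal_times(limb_env)
  rate <- limb_env$rate_hz
  min_len <- cfg$wake_move_min_dur_s * rate

  candidate_runs <- function(th) {
    runs <- logical_runs(v > th)
    if (!nrow(runs)) return(runs[0, ])
    onset_lab <- interval_label_at(bouts, tt[runs$start])
    ok <- !is.na(onset_lab) & onset_lab == "wake" &
      (runs$end - runs$start) >= min_len
    runs[ok, , drop = FALSE]
  }

  cand <- candidate_runs(tw_th)
  if (nrow(cand) == 0L) {
    warning("detect_wake_movements: no candidate movements; falling back to the twitch threshold")
    th <- tw_th
  } else {
    peaks <- vapply(seq_len(nrow(cand)),
                    function(i) max(v[cand$start[i]:(cand$end[i] - 1L)]), numeric(1))
    if (nrow(cand) < cfg$n_reference_movements)
      warning(sprintf(
        "detect_wake_movements: only %d candidate movements (%d requested as reference)",
        nrow(cand), cfg$n_reference_movements))
    ref <- mean(sort(peaks, decreasing = TRUE)[seq_len(min(length(peaks),
                                                           cfg$n_reference_movements))])
    th <- (base + ref) / 2              # midpoint between atonia and movement amplitude
  }
  runs <- candidate_runs(th)
  interval_series(tt[runs$start], tt[runs$end - 1L] + 1 / rate,
                  rep("wake_move", nrow(runs)))
}

#' Per-bout event rates and state-dependency test
#'
#' Computes the event rate in every bout (events/min by default; Hz for
#' spike trains) and, when possible, a Wilcoxon matched-pairs
#' signed-ranks test on successive wake/active-sleep bout pairs (the
#' within-subject state-dependency test; requires `min_pairs` pairs).
#'
#' @param events an [event_series()] (or numeric times).
#' @param bouts a [bout_segmentation()].
#' @param unit `"per_min"` or `"hz"`.
#' @param min_pairs minimum number of successive wake/sleep pairs for the
#'   paired test (default 20).
#' @return list of class `state_rates`: `by_bout` data.frame (state,
#'   onset, offset, n, rate), `state_means` (named mean rate per state),
#'   `wilcoxon` (an `htest`, or `NULL` with `test_available = FALSE` when
#'   there are too few pairs).
#' @export
state_rates <- function(events, bouts, unit = c("per_min", "hz"), min_pairs = 20L) {
  unit <- match.arg(unit)
  times <- if (inherits(events, "event_series")) events$times_s else as.numeric(events)
  per <- if (unit == "per_min") 60 else 1
  n <- vapply(seq_len(nrow(bouts)), function(i)
    sum(times >= bouts$onset_s[i] & times < bouts$offset_s[i]), integer(1))
  dur <- interval_durations(bouts)
  by_bout <- data.frame(state = bouts$label, onset_s = bouts$onset_s,
                        offset_s = bouts$offset_s, n = n, rate = n / dur * per)
  state_means <- tapply(by_bout$rate, by_bout$state, mean)
  # successive wake/active-sleep pairs
  w <- numeric(); s <- numeric()
  i <- 1L
  while (i < nrow(by_bout)) {
    if (by_bout$state[i] != by_bout$state[i + 1L]) {
      pair <- by_bout$rate[i:(i + 1L)]
      if (by_bout$state[i] == "wake") { w <- c(w, pair[1L]); s <- c(s, pair[2L]) }
      else { s <- c(s, pair[1L]); w <- c(w, pair[2L]) }
      i <- i + 2L
    } else i <- i + 1L
  }
  test <- NULL; avail <- FALSE
  if (length(w) >= min_pairs && any(w != s)) {
    test <- stats::wilcox.test(s, w, paired = TRUE, exact = FALSE)
    avail <- TRUE
  }
  structure(list(by_bout = by_bout, state_means = state_means,
                 n_pairs = length(w), wilcoxon = test, test_available = avail,
                 unit = unit),
            class = "state_rates")
}

#' @export
print.state_rates <- function(x, ...) {
  cat("<state_rates>", nrow(x$by_bout), "bouts; mean rate (", x$unit, "):\n")
  print(round(unclass(x$state_means), 3))
  if (x$test_available)
    cat(sprintf("  Wilcoxon matched-pairs (n = %d pairs): V = %g, p = %.4g\n",
                x$n_pairs, x$wilcoxon$statistic, x$wilcoxon$p.value))
  else cat(sprintf("  paired test unavailable (%d pairs)\n", x$n_pairs))
  invisible(x)
}

#' Across-subject paired t test on state means
#'
#' Takes one [state_rates()] result per subject and compares the
#' per-subject mean rates between active sleep and wake with a paired t
#' test (the across-subject state-dependency test).
#'
#' @param rate_list list of `state_rates` objects, one per subject.
#' @return list with `subject_means` data.frame and `t_test` (`htest`).
#' @export
state_rate_test <- function(rate_list) {
  stopifnot(length(rate_list) >= 2L)
  m <- t(vapply(rate_list, function(r)
    c(active_sleep = unname(r$state_means["active_sleep"]),
      wake = unname(r$state_means["wake"])), numeric(2)))
  tt <- stats::t.test(m[, "active_sleep"], m[, "wake"], paired = TRUE)
  list(subject_means = as.data.frame(m), t_test = tt)
}
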