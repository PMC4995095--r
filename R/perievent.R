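# Perievent correlations, interval-jitter surrogates, simultaneous
# acceptance bands, and stimulus-evoked state comparison.

#' Perievent correlation specification
#'
#' Total window span and bin width of a perievent histogram.  The window
#' is centered on the trigger (half before, half after) and must divide
#' into whole bins.  Standard presets via [correlation_preset()].
#'
#' @param window_s total window span, seconds.
#' @param bin_s bin width, seconds.
#' @param name optional preset name.
#' @return list of class `correlation_spec`.
#' @export
correlation_spec <- function(window_s, bin_s, name = "") {
  if (bin_s <= 0) stop("correlation_spec: 'bin_s' must be > 0")
  nb <- window_s / bin_s
  if (abs(nb - round(nb)) > 1e-6 || round(nb) < 1)
    stop("correlation_spec: window must divide into whole bins")
  if (round(nb) %% 2L)
    stop("correlation_spec: window must hold an even number of bins (half before, half after)")
  structure(list(window_s = window_s, bin_s = bin_s, n_bins = as.integer(round(nb)),
                 name = name),
            class = "correlation_spec")
}

#' Standard correlation presets
#'
#' * `smc_spont`: 1000-ms window, 25-ms bins (cortical spontaneous
#'   activity);
#' * `ecn_spont`: 300-ms window, 1-ms bins (brainstem spontaneous
#'   activity);
#' * `stimulation`: 500-ms window, 10-ms bins (stimulus-evoked);
#' * `infusion`: 3000-ms window, 50-ms bins (pre/post-infusion delta
#'   analysis).
#'
#' @param name preset name.
#' @return a [correlation_spec()].
#' @export
correlation_preset <- function(name = c("smc_spont", "ecn_spont", "stimulation", "infusion")) {
  name <- match.arg(name)
  switch(name,
         smc_spont   = correlation_spec(1.0, 0.025, name),
         ecn_spont   = correlation_spec(0.3, 0.001, name),
         stimulation = correlation_spec(0.5, 0.010, name),
         infusion    = correlation_spec(3.0, 0.050, name))
}

#' Interval-jitter specification
#'
#' @param n_surrogates number of surrogate trigger sets (default 1000).
#' @param jitter_window_s width of the fixed partition cells within which
#'   each trigger is resampled uniformly (default 0.5).
#' @param alpha family-wise significance level of the acceptance bands
#'   (default 0.01).
#' @return list of class `jitter_spec`.
#' @export
jitter_spec <- function(n_surrogates = 1000L, jitter_window_s = 0.5, alpha = 0.01) {
  if (n_surrogates < 1L) stop("jitter_spec: 'n_surrogates' must be >= 1")
  if (jitter_window_s <= 0) stop("jitter_spec: 'jitter_window_s' must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("jitter_spec: 'alpha' must be in (0, 1)")
  structure(list(n_surrogates = as.integer(n_surrogates),
                 jitter_window_s = jitter_window_s, alpha = alpha),
            class = "jitter_spec")
}

# Internal: resolve the recording span for edge handling.
resolve_t_range <- function(spikes, triggers, t_range) {
  if (!is.null(t_range)) return(t_range)
  for (x in list(spikes, triggers))
    if (inherits(x, "event_series") && !is.na(x$t0_s) && !is.na(x$duration_s))
      return(c(x$t0_s, x$t0_s + x$duration_s))
  tt <- c(if (inherits(spikes, "event_series")) spikes$times_s else spikes,
          if (inherits(triggers, "event_series")) triggers$times_s else triggers)
  range(tt)
}

# Internal: bin edges of a spec (trigger at 0; bins half-open [left,
# right), right edge inclusive at the window end).
bin_edges <- function(spec) (-(spec$n_bins / 2):(spec$n_bins / 2)) * spec$bin_s

# Internal fast path: perievent counts for a matrix of trigger sets.
# trig_matrix: n_sets x n_triggers.  Returns n_sets x n_bins counts.
perievent_count_matrix <- function(spike_times, trig_matrix, spec) {
  M <- nrow(trig_matrix); K <- ncol(trig_matrix); B <- spec$n_bins
  half <- spec$window_s / 2
  edges <- bin_edges(spec)
  tv <- as.vector(trig_matrix)              # column-major; set id recycles fast
  sid <- rep.int(seq_len(M), K)
  i1 <- findInterval(tv - half, spike_times, left.open = TRUE)
  i2 <- findInterval(tv + half, spike_times)
  cnt <- i2 - i1
  if (sum(cnt) == 0L) return(matrix(0L, M, B))
  idx <- sequence(cnt, from = i1 + 1L)
  dt <- spike_times[idx] - rep.int(tv, cnt)
  b <- findInterval(dt, edges, rightmost.closed = TRUE)
  b <- pmin.int(pmax.int(b, 1L), B)
  flat <- tabulate((rep.int(sid, cnt) - 1L) * B + b, nbins = M * B)
  matrix(flat, nrow = M, ncol = B, byrow = TRUE)
}

#' Perievent spike-rate correlation
#'
#' Histogram of spike rate (Hz) in bins aligned to trigger events:
#' `rate = count / (n_triggers * bin_s)`.  Triggers whose full window
#' does not fit inside the recording span are dropped (their number is
#' reported, not padded).  Bins are half-open `[left, right)` with the
#' right edge inclusive at the window end.
#'
#' @param spikes an [event_series()] (or numeric vector) of spike times.
#' @param triggers an [event_series()] (or numeric vector) of triggers.
#' @param spec a [correlation_spec()] or preset name.
#' @param t_range recording span `c(t0, t1)`; taken from the event-series
#'   metadata when omitted.
#' @return object of class `event_correlation`: `bin_edges_s`, `rate_hz`,
#'   `counts`, `n_triggers`, `n_dropped`, `spec`, and (after
#'   [acceptance_bands()]) `upper_hz`, `lower_hz`, `alpha`.
#' @export
event_correlation <- function(spikes, triggers, spec = correlation_preset("ecn_spont"),
                              t_range = NULL) {
  if (is.character(spec)) spec <- correlation_preset(spec)
  stopifnot(inherits(spec, "correlation_spec"))
  st <- if (inherits(spikes, "event_series")) spikes$times_s else sort(as.numeric(spikes))
  tr <- if (inherits(triggers, "event_series")) triggers$times_s else sort(as.numeric(triggers))
  t_range <- resolve_t_range(spikes, triggers, t_range)
  half <- spec$window_s / 2
  usable <- tr - half >= t_range[1L] & tr + half <= t_range[2L]
  n_dropped <- sum(!usable)
  tr <- tr[usable]
  if (!length(tr))
    stop("event_correlation: no trigger has a full window inside the recording")
  counts <- perievent_count_matrix(st, matrix(tr, nrow = 1L), spec)[1L, ]
  structure(list(bin_edges_s = bin_edges(spec),
                 rate_hz = counts / (length(tr) * spec$bin_s),
                 counts = as.integer(counts),
                 n_triggers = length(tr), n_dropped = n_dropped,
                 spec = spec, upper_hz = NULL, lower_hz = NULL, alpha = NULL),
            class = "event_correlation")
}

#' Bin centers of an event correlation
#' @param x an `event_correlation`.
#' @export
bin_centers <- function(x) {
  e <- x$bin_edges_s
  (e[-1L] + e[-length(e)]) / 2
}

#' @export
print.event_correlation <- function(x, ...) {
  cat(sprintf("<event_correlation%s> %d bins of %g ms, %d triggers (%d dropped)\n",
              if (nzchar(x$spec$name)) paste0(": ", x$spec$name) else "",
              x$spec$n_bins, x$spec$bin_s * 1000, x$n_triggers, x$n_dropped))
  cat(sprintf("  rate: mean %.3f Hz, max %.3f Hz\n", mean(x$rate_hz), max(x$rate_hz)))
  if (!is.null(x$upper_hz)) {
    cr <- band_crossings(x)
    cat(sprintf("  simultaneous bands at alpha = %g: %d bin(s) outside\n",
                x$alpha, length(cr$above) + length(cr$below)))
  }
  invisible(x)
}

#' @export
plot.event_correlation <- function(x, ...) {
  cen <- bin_centers(x)
  ylim <- range(0, x$rate_hz, x$upper_hz, x$lower_hz)
  graphics::plot(cen, x$rate_hz, type = "s", xlab = "time from trigger (s)",
                 ylab = "rate (Hz)", ylim = ylim, ...)
  graphics::abline(v = 0, lty = 3)
  if (!is.null(x$upper_hz)) {
    graphics::lines(cen, x$upper_hz, lty = 2, col = "blue")
    graphics::lines(cen, x$lower_hz, lty = 2, col = "blue")
  }
  invisible(x)
}

#' Interval-jitter surrogate trigger sets
#'
#' Partitions the time axis into contiguous cells of `jitter_window_s`
#' anchored at `t0_s` and resamples every trigger uniformly within its
#' own cell, independently for each surrogate.  Surrogates preserve the
#' trigger count and the per-cell occupancy exactly, destroying timing
#' structure finer than the cell width while preserving coarse rate
#' structure.
#'
#' @param triggers an [event_series()] or numeric trigger times.
#' @param jspec a [jitter_spec()].
#' @param t0_s anchor of the cell partition (recording start).
#' @param seed optional integer seed.
#' @return `n_surrogates x n_triggers` matrix of jittered times.
#' @export
jitter_surrogates <- function(triggers, jspec = jitter_spec(), t0_s = 0, seed = NULL) {
  tr <- if (inherits(triggers, "event_series")) triggers$times_s else as.numeric(triggers)
  if (!length(tr)) stop("jitter_surrogates: no triggers")
  w <- jspec$jitter_window_s
  cell <- floor((tr - t0_s) / w)
  M <- jspec$n_surrogates
  draw <- function() {
    u <- matrix(stats::runif(M * length(tr)), M, length(tr))
    sweep(u, 2L, cell, "+") * w + t0_s
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  attr(out, "cells") <- cell
  attr(out, "jitter_window_s") <- w
  attr(out, "t0_s") <- t0_s
  out
}

#' Simultaneous acceptance bands from jitter surrogates
#'
#' Calibrates family-wise upper and lower bands from the surrogate
#' ensemble by max/min-statistic quantiles: the upper band is the m-th
#' largest of the surrogate maxima over bins (with
#' `m = floor(alpha/2 * (M+1))` for `M` surrogates) and the lower band
#' the m-th smallest of the surrogate minima.  Because the observed
#' correlation is exchangeable with the surrogates under the jitter
#' null, the probability that its rate strictly exceeds the upper band
#' in any bin is at most `m/(M+1) <= alpha/2`, and likewise below the
#' lower band, so the family-wise crossing probability is at most
#' `alpha` regardless of the count distribution.  Per-bin quantile bands
#' cannot give this guarantee at small `alpha` when bins are many
#' relative to surrogates, which is why the bands are flat across bins.
#'
#' @param observed an [event_correlation()].
#' @param surrogates surrogate rates: an `n_surrogates x n_bins` matrix
#'   (Hz) or a list of `event_correlation`s.
#' @param alpha family-wise level (default 0.01); requires
#'   `M >= 2/alpha - 1` surrogates (199 for 0.01).
#' @return `observed` with `upper_hz`, `lower_hz`, `alpha`, `band_m` and
#'   `fwer_bound` filled in.
#' @export
acceptance_bands <- function(observed, surrogates, alpha = 0.01) {
  stopifnot(inherits(observed, "event_correlation"))
  S <- if (is.matrix(surrogates)) surrogates
       else do.call(rbind, lapply(surrogates, function(s) s$rate_hz))
  M <- nrow(S)
  m <- floor(alpha / 2 * (M + 1))
  if (m < 1L)
    stop(sprintf(
      "acceptance_bands: %d surrogates cannot resolve alpha = %g (need >= %d)",
      M, alpha, ceiling(2 / alpha - 1)))
  if (ncol(S) != observed$spec$n_bins)
    stop("acceptance_bands: surrogate bin count does not match the observed correlation")
  hi <- sort(apply(S, 1L, max), decreasing = TRUE)[m]
  lo <- sort(apply(S, 1L, min))[m]
  observed$upper_hz <- rep(hi, ncol(S))
  observed$lower_hz <- rep(lo, ncol(S))
  observed$alpha <- alpha
  observed$band_m <- m
  observed$fwer_bound <- 2 * m / (M + 1)
  observed
}

#' Which bins cross the acceptance bands
#'
#' Crossing is strict: a bin counts only if its rate is strictly above
#' the upper band or strictly below the lower band.
#'
#' @param corr an [event_correlation()] with bands.
#' @return list with integer bin indices `above`, `below`, and logical
#'   `any`.
#' @export
band_crossings <- function(corr) {
  stopifnot(inherits(corr, "event_correlation"))
  if (is.null(corr$upper_hz)) stop("band_crossings: correlation has no bands")
  above <- which(corr$rate_hz > corr$upper_hz)
  below <- which(corr$rate_hz < corr$lower_hz)
  list(above = above, below = below, any = length(above) + length(below) > 0L)
}

#' Perievent correlation with jitter-calibrated bands, in one call
#'
#' Convenience wrapper: computes the observed correlation, generates
#' interval-jitter surrogates of the (usable) triggers, evaluates all
#' surrogate correlations through the same binning path, and attaches
#' simultaneous acceptance bands.
#'
#' @inheritParams event_correlation
#' @param jspec a [jitter_spec()].
#' @param seed optional integer seed for the surrogate draw.
#' @return an [event_correlation()] with bands.
#' @export
jitter_bands <- function(spikes, triggers, spec = correlation_preset("ecn_spont"),
                         jspec = jitter_spec(), t_range = NULL, seed = NULL) {
  if (is.character(spec)) spec <- correlation_preset(spec)
  obs <- event_correlation(spikes, triggers, spec, t_range)
  t_range <- resolve_t_range(spikes, triggers, t_range)
  tr <- if (inherits(triggers, "event_series")) triggers$times_s else sort(as.numeric(triggers))
  half <- spec$window_s / 2
  tr <- tr[tr - half >= t_range[1L] & tr + half <= t_range[2L]]
  surr <- jitter_surrogates(tr, jspec, t0_s = t_range[1L], seed = seed)
  st <- if (inherits(spikes, "event_series")) spikes$times_s else sort(as.numeric(spikes))
  counts <- perievent_count_matrix(st, surr, spec)
  rates <- counts / (length(tr) * spec$bin_s)
  acceptance_bands(obs, rates, alpha = jspec$alpha)
}

#' Peak rate and latency of a perievent correlation
#'
#' Maximum bin rate and its bin-center latency within a search interval
#' (default: the whole post-trigger half-window).  Ties return the
#' earliest latency.
#'
#' @param corr an [event_correlation()].
#' @param search_interval_s `c(lo, hi)` in seconds relative to the
#'   trigger; bins whose centers fall inside (inclusive) are searched.
#' @return list with `peak_hz` and `latency_s`.
#' @export
peak_rate <- function(corr, search_interval_s = NULL) {
  stopifnot(inherits(corr, "event_correlation"))
  if (is.null(search_interval_s))
    search_interval_s <- c(0, corr$spec$window_s / 2)
  cen <- bin_centers(corr)
  sel <- which(cen >= search_interval_s[1L] & cen <= search_interval_s[2L])
  if (!length(sel)) stop("peak_rate: empty search interval")
  i <- sel[which.max(corr$rate_hz[sel])]     # which.max: earliest on ties
  list(peak_hz = corr$rate_hz[i], latency_s = cen[i])
}

#' Trigger-aligned waveform average
#'
#' Mean and SEM across trigger-aligned segments of a continuous signal
#' (e.g. LFP power or EMG power), with optional jitter-calibrated
#' simultaneous bands on the mean.
#'
#' @param sig a [continuous_signal()].
#' @param triggers an [event_series()] or numeric trigger times.
#' @param spec a [correlation_spec()] (only `window_s` is used; the
#'   waveform is sample-resolved).
#' @param jspec optional [jitter_spec()]: when given, surrogate mean
#'   waveforms are computed and simultaneous bands attached.
#' @param seed optional seed for the surrogate draw.
#' @return object of class `waveform_average`: `time_s`, `mean`, `sem`,
#'   `n_triggers`, and optionally `upper`, `lower`, `alpha`.
#' @export
waveform_average <- function(sig, triggers, spec, jspec = NULL, seed = NULL) {
  stopifnot(inherits(sig, "continuous_signal"))
  if (is.character(spec)) spec <- correlation_preset(spec)
  tr <- if (inherits(triggers, "event_series")) triggers$times_s else as.numeric(triggers)
  half <- spec$window_s / 2
  nsamp <- round(spec$window_s * sig$rate_hz)
  n <- length(sig$samples)
  seg_matrix <- function(times) {
    i0 <- round((times - half - sig$t0_s) * sig$rate_hz) + 1
    ok <- i0 >= 1 & (i0 + nsamp - 1) <= n
    i0 <- i0[ok]
    if (!length(i0)) return(NULL)
    idx <- rep(i0, each = nsamp) + rep.int(seq_len(nsamp) - 1L, length(i0))
    matrix(sig$samples[idx], nrow = length(i0), byrow = TRUE)
  }
  m <- seg_matrix(tr)
  if (is.null(m)) stop("waveform_average: no trigger has a full window inside the recording")
  out <- structure(list(
    time_s = (seq_len(nsamp) - 1) / sig$rate_hz - half,
    mean = colMeans(m),
    sem = apply(m, 2L, stats::sd) / sqrt(nrow(m)),
    n_triggers = nrow(m),
    upper = NULL, lower = NULL, alpha = NULL), class = "waveform_average")
  if (!is.null(jspec)) {
    used <- tr[round((tr - half - sig$t0_s) * sig$rate_hz) + 1 >= 1 &
               round((tr - half - sig$t0_s) * sig$rate_hz) + nsamp <= n]
    surr <- jitter_surrogates(used, jspec, t0_s = sig$t0_s, seed = seed)
    S <- t(apply(surr, 1L, function(ts) {
      sm <- seg_matrix(ts)
      if (is.null(sm)) rep(NA_real_, nsamp) else colMeans(sm)
    }))
    S <- S[stats::complete.cases(S), , drop = FALSE]
    fake <- structure(list(bin_edges_s = seq(-half, half, length.out = nsamp + 1L),
                           rate_hz = out$mean,
                           spec = list(n_bins = nsamp)), class = "event_correlation")
    banded <- acceptance_bands(fake, S, alpha = jspec$alpha)
    out$upper <- banded$upper_hz; out$lower <- banded$lower_hz
    out$alpha <- jspec$alpha
  }
  out
}

#' @export
print.waveform_average <- function(x, ...) {
  cat(sprintf("<waveform_average> %d samples over [%.3f, %.3f] s, %d triggers\n",
              length(x$time_s), min(x$time_s), max(x$time_s), x$n_triggers))
  invisible(x)
}

#' @export
plot.waveform_average <- function(x, ...) {
  graphics::plot(x$time_s, x$mean, type = "l", xlab = "time from trigger (s)",
                 ylab = "mean", ...)
  graphics::lines(x$time_s, x$mean + x$sem, lty = 3)
  graphics::lines(x$time_s, x$mean - x$sem, lty = 3)
  if (!is.null(x$upper)) {
    graphics::lines(x$time_s, x$upper, lty = 2, col = "blue")
    graphics::lines(x$time_s, x$lower, lty = 2, col = "blue")
  }
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Stimulation-evoked activity compared across behavioral states
#'
#' For each subject, splits stimulation triggers by the behavioral state
#' they occur in, builds a perievent correlation per state, and extracts
#' the post-trigger peak rate; peaks are then compared across subjects
#' with a paired t test.  Subjects lacking stimulations in either state
#' are excluded with a warning.  Pooled per-state correlations (counts
#' and triggers summed over subjects) are also returned.
#'
#' @param sessions list of subjects; each a list with elements `spikes`,
#'   `stim_times` (event series or numeric) and `bouts`
#'   ([bout_segmentation()]), optionally `t_range`.
#' @param spec a [correlation_spec()] (default: the stimulation preset,
#'   500-ms window, 10-ms bins).
#' @return list of class `stim_state_comparison`: `peaks` data.frame
#'   (subject, state, peak_hz, n_stims), `t_test` (paired, sleep vs
#'   wake), `pooled` (per-state `event_correlation`s), `excluded`.
#' @export
stimulation_state_comparison <- function(sessions, spec = correlation_preset("stimulation")) {
  if (is.character(spec)) spec <- correlation_preset(spec)
  states <- c("active_sleep", "wake")
  peaks <- list(); excluded <- integer()
  pooled_counts <- list(active_sleep = 0, wake = 0)
  pooled_trig <- c(active_sleep = 0L, wake = 0L)
  for (i in seq_along(sessions)) {
    ss <- sessions[[i]]
    st <- if (inherits(ss$stim_times, "event_series")) ss$stim_times$times_s else ss$stim_times
    by_state <- lapply(states, function(s) events_in_state(st, ss$bouts, s))
    names(by_state) <- states
    if (any(vapply(by_state, length, integer(1)) == 0L)) {
      warning(sprintf("stimulation_state_comparison: subject %d lacks stimulations in one state; excluded", i))
      excluded <- c(excluded, i)
      next
    }
    for (s in states) {
      corr <- event_correlation(ss$spikes, by_state[[s]], spec, t_range = ss$t_range)
      pk <- peak_rate(corr)
      peaks[[length(peaks) + 1L]] <-
        data.frame(subject = i, state = s, peak_hz = pk$peak_hz,
                   latency_s = pk$latency_s, n_stims = corr$n_triggers)
      pooled_counts[[s]] <- pooled_counts[[s]] + corr$counts
      pooled_trig[s] <- pooled_trig[s] + corr$n_triggers
    }
  }
  if (!length(peaks))
    stop("stimulation_state_comparison: no subject has stimulations in both states")
  peaks <- do.call(rbind, peaks)
  ps <- peaks$peak_hz[peaks$state == "active_sleep"]
  pw <- peaks$peak_hz[peaks$state == "wake"]
  tt <- if (length(ps) >= 2L && stats::sd(ps - pw) > 0) {
    stats::t.test(ps, pw, paired = TRUE)
  } else if (length(ps) >= 2L && all(ps == pw)) {
    # identical peaks in both states: degenerate paired t of exactly 0
    list(statistic = c(t = 0), p.value = 1, method = "degenerate paired t")
  } else NULL
  pooled <- lapply(states, function(s) {
    structure(list(bin_edges_s = bin_edges(spec),
                   rate_hz = pooled_counts[[s]] / (pooled_trig[s] * spec$bin_s),
                   counts = as.integer(pooled_counts[[s]]),
                   n_triggers = unname(pooled_trig[s]), n_dropped = 0L,
                   spec = spec, upper_hz = NULL, lower_hz = NULL, alpha = NULL),
              class = "event_correlation")
  })
  names(pooled) <- states
  structure(list(peaks = peaks, t_test = tt, pooled = pooled, excluded = excluded),
            class = "stim_state_comparison")
}

#' @export
print.stim_state_comparison <- function(x, ...) {
  cat("<stim_state_comparison>\n")
  agg <- stats::aggregate(peak_hz ~ state, data = x$peaks, FUN = mean)
  print(agg)
  if (!is.null(x$t_test))
    cat(sprintf("  paired t (sleep vs wake peaks): t = %.3f, p = %.4g\n",
                x$t_test$statistic, x$t_test$p.value))
  invisible(x)
}
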