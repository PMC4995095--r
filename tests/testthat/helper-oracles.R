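# Independent oracles and small fixture builders shared across tests.

# Brute-force perievent histogram: nested loop over (trigger, spike)
# pairs, binned with the same half-open edge convention (right edge
# inclusive at the window end).  Deliberately naive; the fast path in
# the package must agree exactly.
brute_force_counts <- function(spike_times, trigger_times, spec, t_range) {
  half <- spec$window_s / 2
  edges <- (-(spec$n_bins / 2):(spec$n_bins / 2)) * spec$bin_s
  counts <- integer(spec$n_bins)
  for (tr in trigger_times) {
    if (tr - half < t_range[1L] || tr + half > t_range[2L]) next
    for (sp in spike_times) {
      dt <- sp - tr
      for (b in seq_len(spec$n_bins)) {
        lo <- edges[b]; hi <- edges[b + 1L]
        inside <- if (b == spec$n_bins) dt >= lo && dt <= hi else dt >= lo && dt < hi
        if (inside) counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

# Expected spike count per trigger in a lag window (a, b], by numerical
# integration of the injected rate function: background plus the
# Gaussian evoked kernel.
expected_window_count <- function(config, class, a, b) {
  k <- evoked_kernel(config, class)
  f <- function(lag) config$spike_background_hz +
    k$amplitude_hz * exp(-(lag - k$latency_s)^2 / (2 * k$width_s^2))
  stats::integrate(f, a, b, rel.tol = 1e-9)$value
}

# Expected rate (Hz) of the injected kernel averaged over analysis bins,
# returning the peak binned rate: the oracle for delta-peak recovery.
binned_kernel_peak <- function(config, class, spec) {
  k <- evoked_kernel(config, class)
  edges <- (-(spec$n_bins / 2):(spec$n_bins / 2)) * spec$bin_s
  f <- function(lag) k$amplitude_hz * exp(-(lag - k$latency_s)^2 / (2 * k$width_s^2))
  rates <- vapply(seq_len(spec$n_bins), function(b)
    stats::integrate(f, edges[b], edges[b + 1L], rel.tol = 1e-9)$value / spec$bin_s,
    numeric(1))
  max(rates)
}

# A flat envelope with rectangular bursts added, as a continuous_signal.
make_env <- function(duration_s, rate_hz = 1000, base = 1,
                     bursts = NULL, wake_level = NULL, wake_iv = NULL) {
  n <- duration_s * rate_hz
  tt <- (seq_len(n) - 1) / rate_hz
  v <- rep(base, n)
  if (!is.null(wake_iv))
    for (i in seq_len(nrow(wake_iv)))
      v[tt >= wake_iv$on[i] & tt < wake_iv$off[i]] <- wake_level
  if (!is.null(bursts))
    for (i in seq_len(nrow(bursts)))
      v[tt >= bursts$on[i] & tt < bursts$off[i]] <- bursts$amp[i]
  continuous_signal(v, rate_hz, 0, "env", "au")
}

# Simple two-bout segmentation helpers.
bouts_sleep_wake <- function(t_split, t_end)
  bout_segmentation(c(0, t_split), c(t_split, t_end), c("active_sleep", "wake"))
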