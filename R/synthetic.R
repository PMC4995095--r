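# Synthetic recording sessions with ground truth.
#
# The generator emulates the statistical structure the analysis stages
# assume: alternating wake (high nuchal tone) / active-sleep (atonia)
# bouts, twitches as point events restricted to atonia, wake movements as
# >= 300 ms high-amplitude bursts restricted to wake, 10-15 Hz spindle
# bursts in the LFP, and an inhomogeneous-Poisson spike train whose
# movement-evoked component can be gated (suppressed during wake) and
# released by an infusion flag.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so every generator channel draws from its own reproducible
#' stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Synthetic session configuration
#'
#' All tunable parameters of the session generator, with validation.
#' Defaults describe a desk-scale neonatal recording: 10-minute session,
#' EMG at 1 kHz, neural channel at 2.5 kHz, minute-scale sleep-wake
#' cycling, twitching at 0.3 Hz during active sleep, wake movements at
#' 0.08 Hz, an evoked-response kernel peaking 100 Hz above a 5 Hz
#' background at 20 ms latency, and wake-movement responses gated.
#'
#' @param duration_s session length, seconds (> 0).
#' @param emg_rate_hz,neural_rate_hz sampling rates, Hz.
#' @param bout_mean_wake_s,bout_mean_sleep_s mean bout durations, seconds;
#'   bouts are drawn from shifted exponentials with a 10 s floor.
#' @param twitch_rate_hz twitch rate during active sleep, events/s.
#' @param wake_move_rate_hz wake-movement rate during wake, events/s.
#' @param wake_move_dur_s mean movement duration, seconds (>= 0.3).
#' @param emg_baseline atonia-level EMG envelope, arbitrary units.
#' @param emg_tone_gain nuchal-tone multiplier during wake (> 1).
#' @param emg_limb_tone_gain residual limb-EMG multiplier during wake.
#' @param twitch_amp_gain twitch peak as a multiple of baseline.
#' @param wake_move_amp_gain movement plateau as a multiple of baseline.
#' @param emg_noise_sd EMG envelope noise SD as a fraction of baseline.
#' @param spike_background_hz baseline firing rate, Hz.
#' @param evoked_latency_s evoked-response latency, seconds.
#' @param evoked_kernel_width_s Gaussian kernel SD, seconds.
#' @param evoked_rate_hz added rate at the kernel peak, Hz.
#' @param gate_wake when `TRUE`, the wake-movement-evoked response is
#'   suppressed (sensory gating engaged).
#' @param infusion_post when `TRUE`, gating is released (post-infusion
#'   condition); twitch and stimulation responses are unaffected.
#' @param stim_times_s optional vector of stimulation times, seconds.
#' @param spindle_rate_hz spindle-burst rate during active sleep, bursts/s.
#' @param spindle_freq_hz spindle frequency, Hz (the detectable band is
#'   10-15 Hz).
#' @param spindle_dur_s spindle-burst duration, seconds; the oscillation
#'   criterion (3 cycles) needs at least `3/spindle_freq_hz` seconds.
#' @param spindle_snr spindle peak amplitude in units of `noise_sd`.
#' @param noise_sd LFP 1/f noise SD.
#' @param seed master integer seed; per-channel streams are derived from
#'   it by fixed offsets.
#' @return validated list of class `session_config`.
#' @export
session_config <- function(duration_s = 600,
                           emg_rate_hz = 1000,
                           neural_rate_hz = 2500,
                           bout_mean_wake_s = 60,
                           bout_mean_sleep_s = 90,
                           twitch_rate_hz = 0.3,
                           wake_move_rate_hz = 0.08,
                           wake_move_dur_s = 0.5,
                           emg_baseline = 1,
                           emg_tone_gain = 5,
                           emg_limb_tone_gain = 1.5,
                           twitch_amp_gain = 5,
                           wake_move_amp_gain = 6,
                           emg_noise_sd = 0.05,
                           spike_background_hz = 5,
                           evoked_latency_s = 0.02,
                           evoked_kernel_width_s = 0.01,
                           evoked_rate_hz = 100,
                           gate_wake = TRUE,
                           infusion_post = FALSE,
                           stim_times_s = NULL,
                           spindle_rate_hz = 0.1,
                           spindle_freq_hz = 12,
                           spindle_dur_s = 0.5,
                           spindle_snr = 10,
                           noise_sd = 1,
                           seed = 1L) {
  cfg <- list(duration_s = duration_s, emg_rate_hz = emg_rate_hz,
              neural_rate_hz = neural_rate_hz,
              bout_mean_wake_s = bout_mean_wake_s,
              bout_mean_sleep_s = bout_mean_sleep_s,
              twitch_rate_hz = twitch_rate_hz,
              wake_move_rate_hz = wake_move_rate_hz,
              wake_move_dur_s = wake_move_dur_s,
              emg_baseline = emg_baseline, emg_tone_gain = emg_tone_gain,
              emg_limb_tone_gain = emg_limb_tone_gain,
              twitch_amp_gain = twitch_amp_gain,
              wake_move_amp_gain = wake_move_amp_gain,
              emg_noise_sd = emg_noise_sd,
              spike_background_hz = spike_background_hz,
              evoked_latency_s = evoked_latency_s,
              evoked_kernel_width_s = evoked_kernel_width_s,
              evoked_rate_hz = evoked_rate_hz,
              gate_wake = isTRUE(gate_wake), infusion_post = isTRUE(infusion_post),
              stim_times_s = if (is.null(stim_times_s)) NULL else sort(as.numeric(stim_times_s)),
              spindle_rate_hz = spindle_rate_hz, spindle_freq_hz = spindle_freq_hz,
              spindle_dur_s = spindle_dur_s, spindle_snr = spindle_snr,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_session_config(cfg)
  structure(cfg, class = "session_config")
}

# Internal: configuration errors name the offending field.
validate_session_config <- function(cfg) {
  pos1 <- function(f) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("session_config: field '%s' must be a finite number", f))
    v
  }
  if (pos1("duration_s") <= 0) stop("session_config: field 'duration_s' must be > 0")
  for (f in c("emg_rate_hz", "neural_rate_hz", "emg_baseline"))
    if (pos1(f) <= 0)
      stop(sprintf("session_config: field '%s' must be positive", f))
  for (f in c("twitch_rate_hz", "wake_move_rate_hz", "spike_background_hz",
              "evoked_rate_hz", "spindle_rate_hz", "emg_noise_sd", "spindle_snr",
              "noise_sd"))
    if (pos1(f) < 0) stop(sprintf("session_config: field '%s' must be >= 0", f))
  for (f in c("bout_mean_wake_s", "bout_mean_sleep_s", "evoked_kernel_width_s",
              "spindle_dur_s", "twitch_amp_gain", "wake_move_amp_gain",
              "emg_limb_tone_gain"))
    if (pos1(f) <= 0) stop(sprintf("session_config: field '%s' must be > 0", f))
  if (pos1("emg_tone_gain") <= 1) stop("session_config: field 'emg_tone_gain' must be > 1")
  if (pos1("wake_move_dur_s") < 0.3)
    stop("session_config: field 'wake_move_dur_s' must be >= 0.3")
  fs <- pos1("spindle_freq_hz")
  if (fs <= 0 || fs >= cfg$neural_rate_hz / 2)
    stop("session_config: field 'spindle_freq_hz' must lie in (0, neural_rate_hz/2)")
  pos1("evoked_latency_s")
  invisible(cfg)
}

#' Injected evoked-response kernel for a trigger class
#'
#' The generator adds, for every trigger of a class, a Gaussian rate
#' kernel `amplitude * exp(-(lag - latency)^2 / (2 width^2))` (Hz) to the
#' background rate.  The wake-movement amplitude is zero while gating is
#' engaged (`gate_wake` and not `infusion_post`); stimulation responses
#' are state-independent.
#'
#' @param config a [session_config()].
#' @param class one of `"twitch"`, `"wake_move"`, `"stimulation"`.
#' @return list with `amplitude_hz`, `latency_s`, `width_s`.
#' @export
evoked_kernel <- function(config, class = c("twitch", "wake_move", "stimulation")) {
  class <- match.arg(class)
  amp <- config$evoked_rate_hz
  if (class == "wake_move" && config$gate_wake && !config$infusion_post) amp <- 0
  list(amplitude_hz = amp, latency_s = config$evoked_latency_s,
       width_s = config$evoked_kernel_width_s)
}

# ---- bout and event scheduling ------------------------------------------

#' Generate an alternating wake / active-sleep bout sequence
#'
#' Bout durations are shifted exponentials (10 s floor plus an
#' exponential with the remaining mean), alternating between states from
#' a randomly drawn initial state; the final bout is truncated at the
#' session end.
#'
#' @param config a [session_config()].
#' @param seed integer seed (defaults to a fixed offset of the config seed).
#' @return a [bout_segmentation()].
#' @export
generate_bouts <- function(config, seed = config$seed + 101L) {
  min_bout <- 10
  with_seed(seed, {
    state <- if (stats::runif(1) < 0.5) "wake" else "active_sleep"
    on <- numeric(); off <- numeric(); lab <- character(); t <- 0
    while (t < config$duration_s) {
      m <- if (state == "wake") config$bout_mean_wake_s else config$bout_mean_sleep_s
      d <- min_bout + stats::rexp(1, 1 / max(m - min_bout, 1e-3))
      d <- min(d, config$duration_s - t)
      on <- c(on, t); off <- c(off, t + d); lab <- c(lab, state)
      t <- t + d
      state <- if (state == "wake") "active_sleep" else "wake"
    }
    bout_segmentation(on, off, lab)
  })
}

# Internal: Poisson point events inside bouts of one state, with an edge
# margin and a minimum separation.
schedule_events <- function(bouts, state, rate_hz, margin_s = 0.5, min_sep_s = 0.25) {
  if (rate_hz <= 0) return(numeric())
  out <- numeric()
  sel <- bouts[bouts$label == state, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    lo <- sel$onset_s[i] + margin_s; hi <- sel$offset_s[i] - margin_s
    if (hi <= lo) next
    n <- stats::rpois(1, rate_hz * (hi - lo))
    if (n == 0) next
    tt <- sort(stats::runif(n, lo, hi))
    keep <- c(TRUE, diff(tt) >= min_sep_s)
    out <- c(out, tt[keep])
  }
  sort(out)
}

# Internal: non-overlapping intervals inside bouts of one state.
schedule_intervals <- function(bouts, state, rate_hz, mean_dur_s, min_dur_s,
                               margin_s = 0.5, min_gap_s = 0.25) {
  if (rate_hz <= 0) return(interval_series())
  on <- numeric(); off <- numeric()
  sel <- bouts[bouts$label == state, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    lo <- sel$onset_s[i] + margin_s; hi <- sel$offset_s[i] - margin_s
    if (hi <= lo) next
    n <- stats::rpois(1, rate_hz * (hi - lo))
    if (n == 0) next
    starts <- sort(stats::runif(n, lo, hi))
    durs <- min_dur_s + stats::rexp(n, 1 / max(mean_dur_s - min_dur_s, 1e-3))
    last_end <- -Inf
    for (j in seq_len(n)) {
      s <- starts[j]; e <- s + durs[j]
      if (s < last_end + min_gap_s || e > hi) next
      on <- c(on, s); off <- c(off, e); last_end <- e
    }
  }
  interval_series(on, off, rep("", length(on)))
}

# ---- channel synthesis ---------------------------------------------------

#' Synthesize a rectified EMG envelope channel
#'
#' The envelope is built directly in rectified-envelope space: a
#' state-dependent base level (`emg_baseline` during atonia,
#' `emg_baseline * tone_gain` during wake), 100 ms raised-cosine bumps
#' peaking at `twitch_amp_gain * emg_baseline` for twitches (wide enough
#' that the analysis-side 10 ms envelope smoothing attenuates the peak
#' by under 5%, keeping the amplitude criterion decisive), plateaus at
#' `wake_move_amp_gain * emg_baseline` with 20 ms ramps for movements,
#' plus Gaussian envelope noise clamped at zero.  The analysis path
#' treats it exactly like a rectified real EMG.
#'
#' @param bouts a [bout_segmentation()].
#' @param twitches numeric twitch times (must lie in active-sleep bouts).
#' @param movements an [interval_series()] of movements (must lie in wake
#'   bouts).
#' @param config a [session_config()].
#' @param seed integer seed.
#' @param tone_gain wake-tone multiplier for this channel: the nuchal
#'   channel carries the full `emg_tone_gain`, limb channels only
#'   `emg_limb_tone_gain`.
#' @param label channel label.
#' @return a [continuous_signal()] envelope.
#' @export
generate_emg <- function(bouts, twitches, movements, config,
                         seed = config$seed + 303L,
                         tone_gain = config$emg_tone_gain,
                         label = "emg") {
  lab <- interval_label_at(bouts, twitches)
  if (any(is.na(lab) | lab != "active_sleep"))
    stop("generate_emg: twitch scheduled outside an active-sleep bout")
  if (nrow(movements)) {
    mlab <- interval_label_at(bouts, movements$onset_s)
    if (any(is.na(mlab) | mlab != "wake"))
      stop("generate_emg: movement scheduled outside a wake bout")
  }
  n <- round(config$duration_s * config$emg_rate_hz)
  tt <- (seq_len(n) - 1) / config$emg_rate_hz
  base <- config$emg_baseline
  lev <- ifelse(interval_label_at(bouts, tt) == "wake", base * tone_gain, base)
  lev[is.na(lev)] <- base
  env <- lev
  half <- 0.05                          # 100 ms raised-cosine twitch bump
  for (tw in twitches) {
    i <- which(tt >= tw - half & tt <= tw + half)
    env[i] <- env[i] + (config$twitch_amp_gain - 1) * base *
      0.5 * (1 + cos(pi * (tt[i] - tw) / half))
  }
  ramp <- 0.02                          # movement plateau with 20 ms ramps
  for (j in seq_len(nrow(movements))) {
    on <- movements$onset_s[j]; off <- movements$offset_s[j]
    i <- which(tt >= on & tt < off)
    shape <- pmin(1, pmin(tt[i] - on, off - tt[i]) / ramp)
    env[i] <- env[i] + (config$wake_move_amp_gain - tone_gain) * base * shape
  }
  if (config$emg_noise_sd > 0) {
    env <- with_seed(seed, env + stats::rnorm(n, 0, config$emg_noise_sd * base))
    env <- pmax(env, 0)
  }
  continuous_signal(env, config$emg_rate_hz, 0, label, "au")
}

#' Synthesize a spike train as an inhomogeneous Poisson process
#'
#' Background homogeneous Poisson at `spike_background_hz` plus, for each
#' trigger of each class, a Gaussian rate kernel ([evoked_kernel()]).
#' Superposition of independent Poisson processes makes the sum an exact
#' inhomogeneous Poisson draw: each trigger contributes
#' `Poisson(amplitude * width * sqrt(2*pi))` spikes at
#' `Normal(trigger + latency, width)` times.
#'
#' @param triggers_by_class named list with any of `twitch`, `wake_move`,
#'   `stimulation`: numeric trigger times.
#' @param config a [session_config()].
#' @param seed integer seed.
#' @param duration_s session span (defaults to `config$duration_s`).
#' @return an [event_series()] of spike times with span metadata.
#' @export
generate_spikes <- function(triggers_by_class, config,
                            seed = config$seed + 707L,
                            duration_s = config$duration_s) {
  bad <- setdiff(names(triggers_by_class), c("twitch", "wake_move", "stimulation"))
  if (length(bad))
    stop("generate_spikes: unknown trigger class: ", paste(bad, collapse = ", "))
  if (config$spike_background_hz < 0 || config$evoked_rate_hz < 0)
    stop("generate_spikes: rates must be nonnegative")
  with_seed(seed, {
    nbg <- stats::rpois(1, config$spike_background_hz * duration_s)
    spikes <- stats::runif(nbg, 0, duration_s)
    for (cls in names(triggers_by_class)) {
      k <- evoked_kernel(config, cls)
      if (k$amplitude_hz <= 0) next
      mass <- k$amplitude_hz * k$width_s * sqrt(2 * pi)
      for (tr in triggers_by_class[[cls]]) {
        m <- stats::rpois(1, mass)
        if (m == 0) next
        s <- stats::rnorm(m, tr + k$latency_s, k$width_s)
        spikes <- c(spikes, s[s >= 0 & s < duration_s])
      }
    }
    event_series(sort(spikes), label = "spikes", t0_s = 0, duration_s = duration_s)
  })
}

#' Synthesize an LFP channel with spindle bursts
#'
#' 1/f-shaped Gaussian noise (spectrum amplitude proportional to
#' `1/sqrt(max(f, 1 Hz))`, rescaled to `noise_sd`) plus, inside each
#' spindle interval, a sinusoid at `spindle_freq_hz` with peak amplitude
#' `spindle_snr * noise_sd` (amplitude 1 when `noise_sd = 0`) under a
#' plateau envelope with 50 ms raised-cosine ramps, so that a burst
#' satisfying the duration criterion also spends essentially its whole
#' extent above an RMS detection threshold.
#'
#' @param spindle_intervals an [interval_series()] of burst intervals
#'   (non-overlapping).
#' @param config a [session_config()].
#' @param seed integer seed.
#' @param duration_s session span.
#' @return a [continuous_signal()] at `neural_rate_hz`.
#' @export
generate_lfp <- function(spindle_intervals, config,
                         seed = config$seed + 606L,
                         duration_s = config$duration_s) {
  if (config$spindle_freq_hz <= 0 || config$spindle_freq_hz >= config$neural_rate_hz / 2)
    stop("generate_lfp: spindle_freq_hz outside (0, neural_rate_hz/2)")
  n <- round(duration_s * config$neural_rate_hz)
  y <- numeric(n)
  if (config$noise_sd > 0) {
    y <- with_seed(seed, {
      w <- stats::rnorm(n)
      f <- seq(0, config$neural_rate_hz, length.out = n + 1)[seq_len(n)]
      f <- pmin(f, config$neural_rate_hz - f)    # two-sided frequency axis
      shape <- 1 / sqrt(pmax(f, 1))
      shape[1L] <- 0                             # no DC
      v <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
      v * (config$noise_sd / stats::sd(v))
    })
  }
  amp <- if (config$noise_sd > 0) config$spindle_snr * config$noise_sd else 1
  tt <- (seq_len(n) - 1) / config$neural_rate_hz
  for (j in seq_len(nrow(spindle_intervals))) {
    on <- spindle_intervals$onset_s[j]; off <- spindle_intervals$offset_s[j]
    i <- which(tt >= on & tt < off)
    ramp_s <- min(0.05, (off - on) / 4)
    edge <- pmin(tt[i] - on, off - tt[i])
    shape <- ifelse(edge >= ramp_s, 1, 0.5 * (1 - cos(pi * edge / ramp_s)))
    y[i] <- y[i] + amp * shape *
      sin(2 * pi * config$spindle_freq_hz * (tt[i] - on))
  }
  continuous_signal(y, config$neural_rate_hz, 0, "lfp", "au")
}

# ---- full session --------------------------------------------------------

#' Generate a complete synthetic session with ground truth
#'
#' Draws the bout sequence, schedules twitches (forelimb and hindlimb),
#' wake movements and spindle bursts inside the appropriate states, then
#' synthesizes the requested channels.  Each channel uses its own RNG
#' stream derived from `config$seed` by a fixed offset, so the whole
#' session is bit-reproducible and channels can be regenerated
#' independently.
#'
#' @param config a [session_config()].
#' @param channels which channels to synthesize; omitting expensive
#'   channels (EMG, LFP) makes event-level simulation studies cheap.
#' @return list of class `twitch_session` with elements `recording`
#'   (named list: `nuchal_emg`, `forelimb_emg`, `hindlimb_emg`
#'   [continuous_signal()]s, `lfp`, and `spikes` [event_series()]) and
#'   `truth` (class `session_truth`: `bouts`, `twitch_times_s`,
#'   `hindlimb_twitch_times_s`, `wake_move_intervals`,
#'   `spindle_intervals`, `stim_times_s`, `kernels`, `config`).
#' @export
generate_session <- function(config,
                             channels = c("nuchal_emg", "forelimb_emg",
                                          "hindlimb_emg", "lfp", "spikes")) {
  stopifnot(inherits(config, "session_config"))
  channels <- match.arg(channels, several.ok = TRUE)
  bouts <- generate_bouts(config)
  ev <- with_seed(config$seed + 202L, list(
    twitch = schedule_events(bouts, "active_sleep", config$twitch_rate_hz),
    hl_twitch = schedule_events(bouts, "active_sleep", config$twitch_rate_hz),
    moves = schedule_intervals(bouts, "wake", config$wake_move_rate_hz,
                               config$wake_move_dur_s, 0.3),
    spindles = schedule_intervals(bouts, "active_sleep", config$spindle_rate_hz,
                                  config$spindle_dur_s, config$spindle_dur_s,
                                  min_gap_s = 0.25)
  ))
  stim <- config$stim_times_s
  truth <- structure(list(
    bouts = bouts,
    twitch_times_s = ev$twitch,
    hindlimb_twitch_times_s = ev$hl_twitch,
    wake_move_intervals = ev$moves,
    spindle_intervals = ev$spindles,
    stim_times_s = stim,
    kernels = list(twitch = evoked_kernel(config, "twitch"),
                   wake_move = evoked_kernel(config, "wake_move"),
                   stimulation = evoked_kernel(config, "stimulation")),
    config = config), class = "session_truth")

  rec <- list()
  if ("nuchal_emg" %in% channels)
    rec$nuchal_emg <- generate_emg(bouts, numeric(), interval_series(), config,
                                   seed = config$seed + 303L,
                                   tone_gain = config$emg_tone_gain, label = "nuchal_emg")
  if ("forelimb_emg" %in% channels)
    rec$forelimb_emg <- generate_emg(bouts, ev$twitch, ev$moves, config,
                                     seed = config$seed + 404L,
                                     tone_gain = config$emg_limb_tone_gain,
                                     label = "forelimb_emg")
  if ("hindlimb_emg" %in% channels)
    rec$hindlimb_emg <- generate_emg(bouts, ev$hl_twitch, interval_series(), config,
                                     seed = config$seed + 505L,
                                     tone_gain = config$emg_limb_tone_gain,
                                     label = "hindlimb_emg")
  if ("lfp" %in% channels)
    rec$lfp <- generate_lfp(ev$spindles, config)
  if ("spikes" %in% channels) {
    trig <- list(twitch = ev$twitch,
                 wake_move = ev$moves$onset_s)
    if (!is.null(stim)) trig$stimulation <- stim
    rec$spikes <- generate_spikes(trig, config)
  }
  structure(list(recording = rec, truth = truth), class = "twitch_session")
}

#' Generate a pre/post infusion session pair
#'
#' Simulates the infusion experiment: a pre epoch generated with the
#' base configuration (gating engaged when `gate_wake = TRUE`) and a
#' post epoch in which, for the drug group, `infusion_post = TRUE`
#' releases the gate on wake-movement-evoked responses; the saline group
#' is unchanged.  Motor statistics (bout structure, twitch and movement
#' rates) are drawn from the same distributions in both epochs: the
#' infusion affects only gating.  Post-epoch times are shifted so the
#' pair tiles `[0, pre + post)`.
#'
#' @param config a [session_config()]; `duration_s` is overridden by the
#'   design epochs.
#' @param design an [infusion_design()].
#' @param channels channels to synthesize (default spikes only, which is
#'   what the delta analysis consumes).
#' @return list of class `infusion_session`: `pre`, `post`
#'   (`twitch_session`s, post shifted), `design`, and `combined` (merged
#'   `spikes`, `twitch_times_s`, `wake_move_intervals`, `bouts`).
#' @export
generate_infusion_session <- function(config, design = infusion_design(),
                                      channels = "spikes") {
  stopifnot(inherits(config, "session_config"))
  shift_session <- function(sess, dt) {
    tr <- sess$truth
    tr$bouts <- bout_segmentation(tr$bouts$onset_s + dt, tr$bouts$offset_s + dt,
                                  tr$bouts$label)
    tr$twitch_times_s <- tr$twitch_times_s + dt
    tr$hindlimb_twitch_times_s <- tr$hindlimb_twitch_times_s + dt
    tr$wake_move_intervals <- interval_series(tr$wake_move_intervals$onset_s + dt,
                                              tr$wake_move_intervals$offset_s + dt,
                                              tr$wake_move_intervals$label)
    tr$spindle_intervals <- interval_series(tr$spindle_intervals$onset_s + dt,
                                            tr$spindle_intervals$offset_s + dt,
                                            tr$spindle_intervals$label)
    if (!is.null(tr$stim_times_s)) tr$stim_times_s <- tr$stim_times_s + dt
    sess$truth <- tr
    for (nm in names(sess$recording)) {
      ch <- sess$recording[[nm]]
      if (inherits(ch, "continuous_signal")) ch$t0_s <- ch$t0_s + dt
      else if (inherits(ch, "event_series")) {
        ch <- event_series(ch$times_s + dt, ch$label, t0_s = ch$t0_s + dt,
                           duration_s = ch$duration_s)
      }
      sess$recording[[nm]] <- ch
    }
    sess
  }
  mk_cfg <- function(dur, seed, post) {
    cfg <- unclass(config)
    cfg$duration_s <- dur
    cfg$seed <- seed
    cfg$infusion_post <- post && design$group == "drug"
    do.call(session_config, cfg[setdiff(names(cfg), character())])
  }
  pre_dur <- diff(design$pre_interval); post_dur <- diff(design$post_interval)
  pre <- generate_session(mk_cfg(pre_dur, config$seed, FALSE), channels = channels)
  post <- generate_session(mk_cfg(post_dur, config$seed + 50000L, TRUE), channels = channels)
  post <- shift_session(post, design$post_interval[1L])
  total <- design$post_interval[2L]
  combined <- list(
    spikes = if ("spikes" %in% channels)
      event_series(c(pre$recording$spikes$times_s, post$recording$spikes$times_s),
                   "spikes", t0_s = 0, duration_s = total),
    twitch_times_s = c(pre$truth$twitch_times_s, post$truth$twitch_times_s),
    wake_move_intervals = interval_series(
      c(pre$truth$wake_move_intervals$onset_s, post$truth$wake_move_intervals$onset_s),
      c(pre$truth$wake_move_intervals$offset_s, post$truth$wake_move_intervals$offset_s),
      c(pre$truth$wake_move_intervals$label, post$truth$wake_move_intervals$label)),
    bouts = bout_segmentation(
      c(pre$truth$bouts$onset_s, post$truth$bouts$onset_s),
      c(pre$truth$bouts$offset_s, post$truth$bouts$offset_s),
      c(pre$truth$bouts$label, post$truth$bouts$label)))
  structure(list(pre = pre, post = post, design = design, combined = combined),
            class = "infusion_session")
}

#' @export
print.twitch_session <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<twitch_session> %.0f s, %d bouts, %d twitches, %d wake movements, %d spindles\n",
              cfg$duration_s, nrow(x$truth$bouts), length(x$truth$twitch_times_s),
              nrow(x$truth$wake_move_intervals), nrow(x$truth$spindle_intervals)))
  cat("  channels:", paste(names(x$recording), collapse = ", "), "\n")
  invisible(x)
}
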