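test_that("session_config validation names the offending field", {
  expect_error(session_config(duration_s = -1), "duration_s")
  expect_error(session_config(twitch_rate_hz = -0.1), "twitch_rate_hz")
  expect_error(session_config(emg_tone_gain = 0.9), "emg_tone_gain")
  expect_error(session_config(wake_move_dur_s = 0.2), "wake_move_dur_s")
  expect_error(session_config(spindle_freq_hz = 2000), "spindle_freq_hz")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- session_config(duration_s = 60, seed = 12)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a, b)
})

test_that("ground-truth events respect the bout states", {
  for (sd in c(1, 5, 9)) {
    s <- generate_session(session_config(duration_s = 300, seed = sd),
                          channels = "spikes")
    tr <- s$truth
    expect_true(all(interval_label_at(tr$bouts, tr$twitch_times_s) == "active_sleep"))
    if (nrow(tr$wake_move_intervals))
      expect_true(all(interval_label_at(tr$bouts, tr$wake_move_intervals$onset_s) == "wake"))
    if (nrow(tr$spindle_intervals))
      expect_true(all(interval_label_at(tr$bouts, tr$spindle_intervals$onset_s) == "active_sleep"))
    # bouts tile the session
    expect_equal(tr$bouts$onset_s[1], 0)
    expect_equal(tr$bouts$offset_s[nrow(tr$bouts)], 300)
  }
})

test_that("a null session is baseline EMG plus homogeneous Poisson spiking", {
  cfg <- session_config(duration_s = 400, twitch_rate_hz = 0, wake_move_rate_hz = 0,
                        spindle_rate_hz = 0, spike_background_hz = 5, seed = 4)
  s <- generate_session(cfg, channels = c("forelimb_emg", "spikes"))
  env <- s$recording$forelimb_emg
  sleep_idx <- interval_label_at(s$truth$bouts, signal_times(env)) == "active_sleep"
  expect_equal(mean(env$samples[which(sleep_idx)]), cfg$emg_baseline, tolerance = 0.01)
  n <- length(s$recording$spikes)
  expect_lt(abs(n - 5 * 400), 3 * sqrt(5 * 400))
})

test_that("twitch-evoked spiking matches the integrated injected kernel", {
  cfg <- session_config(duration_s = 600, gate_wake = TRUE, infusion_post = FALSE,
                        evoked_latency_s = 0.02, seed = 7)
  s <- generate_session(cfg, channels = "spikes")
  sp <- s$recording$spikes$times_s
  count_after <- function(times, a, b)
    vapply(times, function(t0) sum(sp > t0 + a & sp <= t0 + b), numeric(1))
  tw <- count_after(s$truth$twitch_times_s, 0.01, 0.05)
  mv <- count_after(s$truth$wake_move_intervals$onset_s, 0.01, 0.05)
  exp_tw <- expected_window_count(cfg, "twitch", 0.01, 0.05)
  exp_mv <- expected_window_count(cfg, "wake_move", 0.01, 0.05)
  expect_gt(mean(tw), mean(mv))
  expect_lt(abs(mean(tw) - exp_tw), 3 * stats::sd(tw) / sqrt(length(tw)))
  expect_lt(abs(mean(mv) - exp_mv), 3 * stats::sd(mv) / sqrt(max(length(mv), 1)) + 0.05)
})

test_that("gating suppresses the wake-movement kernel and infusion releases it", {
  gated <- evoked_kernel(session_config(gate_wake = TRUE, infusion_post = FALSE), "wake_move")
  expect_equal(gated$amplitude_hz, 0)
  released <- evoked_kernel(session_config(gate_wake = TRUE, infusion_post = TRUE), "wake_move")
  expect_equal(released$amplitude_hz, 100)
  stim <- evoked_kernel(session_config(gate_wake = TRUE, infusion_post = FALSE), "stimulation")
  expect_equal(stim$amplitude_hz, 100)
})

test_that("background-only spike generation is Poisson at the nominal rate", {
  cfg <- session_config(duration_s = 100, spike_background_hz = 5, seed = 2)
  sp <- generate_spikes(list(), cfg, seed = 99, duration_s = 100)
  expect_lt(abs(length(sp) - 500), 3 * sqrt(500))
  expect_error(generate_spikes(list(bogus = 1), cfg), "unknown trigger class")
})

test_that("generate_emg rejects events inconsistent with the bouts", {
  cfg <- session_config(duration_s = 60, emg_noise_sd = 0, seed = 1)
  bouts <- bout_segmentation(c(0, 30), c(30, 60), c("wake", "active_sleep"))
  expect_error(generate_emg(bouts, twitches = 10, interval_series(), cfg),
               "twitch scheduled outside")
  # no events, zero noise: exactly the two tone levels
  env <- generate_emg(bouts, numeric(), interval_series(), cfg)
  expect_equal(sort(unique(env$samples)), c(1, 5))
})

test_that("a clean LFP burst carries its frequency; silence is exact zero", {
  cfg <- session_config(duration_s = 10, noise_sd = 0, spindle_freq_hz = 12, seed = 3)
  lfp <- generate_lfp(interval_series(4, 4.3), cfg, duration_s = 10)
  idx <- which(signal_times(lfp) >= 4 & signal_times(lfp) < 4.3)
  seg <- continuous_signal(lfp$samples[idx], lfp$rate_hz)
  expect_lt(abs(dominant_frequency(seg, c(1, 40), min_cycles = 0) - 12), 1)
  silent <- generate_lfp(interval_series(), cfg, duration_s = 2)
  expect_true(all(silent$samples == 0))
})

test_that("empirical background rate converges with duration", {
  cfg_short <- session_config(duration_s = 50, twitch_rate_hz = 0, wake_move_rate_hz = 0,
                              spindle_rate_hz = 0, seed = 8)
  cfg_long <- session_config(duration_s = 2000, twitch_rate_hz = 0, wake_move_rate_hz = 0,
                             spindle_rate_hz = 0, seed = 8)
  r_short <- length(generate_session(cfg_short, channels = "spikes")$recording$spikes) / 50
  r_long <- length(generate_session(cfg_long, channels = "spikes")$recording$spikes) / 2000
  expect_lt(abs(r_long - 5), abs(r_short - 5) + 0.15)
  expect_lt(abs(r_long - 5), 3 * sqrt(5 / 2000))
})
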