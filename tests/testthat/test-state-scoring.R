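test_that("score_tone splits a stepped envelope at the right boundaries", {
  env <- make_env(90, base = 1, wake_level = 5,
                  wake_iv = data.frame(on = 30, off = 60))
  b <- score_tone(env)
  expect_equal(nrow(b), 3L)
  expect_equal(b$label, c("active_sleep", "wake", "active_sleep"))
  expect_lt(abs(b$onset_s[2] - 30), 0.1)
  expect_lt(abs(b$onset_s[3] - 60), 0.1)
})

test_that("score_tone degrades gracefully on a flat envelope", {
  env <- make_env(30, base = 2)
  expect_warning(b <- score_tone(env), "degenerate")
  expect_equal(nrow(b), 1L)
})

test_that("sub-minimum bouts are absorbed into their neighbors", {
  env <- make_env(60, base = 1, wake_level = 5,
                  wake_iv = data.frame(on = 29, off = 31))  # 2 s blip
  b <- score_tone(env, scoring_config(min_bout_s = 5))
  expect_equal(nrow(b), 1L)
  expect_equal(b$label, "active_sleep")
})

test_that("twitches require >3x baseline amplitude during atonia", {
  bouts <- bouts_sleep_wake(60, 120)
  # excursion to 3.5x baseline in sleep -> one twitch
  env <- make_env(120, base = 1, bursts = data.frame(on = 20, off = 20.03, amp = 3.5))
  expect_equal(length(detect_twitches(env, bouts)), 1L)
  # 2.9x stays below the strict 3x criterion
  env2 <- make_env(120, base = 1, bursts = data.frame(on = 20, off = 20.03, amp = 2.9))
  expect_equal(length(detect_twitches(env2, bouts)), 0L)
  # suprathreshold excursion during wake is not a twitch
  env3 <- make_env(120, base = 1, bursts = data.frame(on = 80, off = 80.03, amp = 3.5))
  expect_equal(length(detect_twitches(env3, bouts)), 0L)
})

test_that("twitch events honor the refractory period", {
  bouts <- bouts_sleep_wake(60, 120)
  env <- make_env(120, base = 1,
                  bursts = data.frame(on = c(20, 20.05), off = c(20.02, 20.07),
                                      amp = c(4, 4)))
  expect_equal(length(detect_twitches(env, bouts)), 1L)
})

test_that("wake movements use the midpoint threshold and the 300 ms rule", {
  bouts <- bout_segmentation(c(0, 60), c(60, 120), c("active_sleep", "wake"))
  env <- make_env(120, base = 1, bursts = data.frame(on = 80, off = 80.4, amp = 6))
  expect_warning(mv <- detect_wake_movements(env, bouts), "candidate")
  expect_equal(nrow(mv), 1L)
  # onset at the first crossing of (1 + 6)/2 = 3.5: the burst is a step,
  # so the onset is the step time itself
  expect_lt(abs(mv$onset_s[1] - 80), 0.005)
  expect_gte(mv$offset_s[1] - mv$onset_s[1], 0.3)
  # 200 ms burst is too short
  env2 <- make_env(120, base = 1, bursts = data.frame(on = 80, off = 80.2, amp = 6))
  expect_warning(mv2 <- detect_wake_movements(env2, bouts), "no candidate")
  expect_equal(nrow(mv2), 0L)
  # 400 ms burst during atonia is not a wake movement
  env3 <- make_env(120, base = 1, bursts = data.frame(on = 20, off = 20.4, amp = 6))
  expect_warning(mv3 <- detect_wake_movements(env3, bouts), "no candidate")
  expect_equal(nrow(mv3), 0L)
})

test_that("detection is invariant to global envelope scaling", {
  bouts <- bouts_sleep_wake(60, 120)
  env <- make_env(120, base = 1,
                  bursts = data.frame(on = c(10, 40), off = c(10.03, 40.03), amp = 4))
  scaled <- continuous_signal(env$samples * 7.3, env$rate_hz)
  t1 <- detect_twitches(env, bouts)
  t2 <- detect_twitches(scaled, bouts)
  expect_equal(t1$times_s, t2$times_s)
})

test_that("generator round-trip: strong twitches recovered, weak ones never", {
  recovered <- function(gain, sd) {
    cfg <- session_config(duration_s = 600, twitch_amp_gain = gain, seed = sd,
                          spindle_rate_hz = 0)
    s <- generate_session(cfg, channels = c("nuchal_emg", "forelimb_emg"))
    bouts <- score_tone(rectify_smooth(s$recording$nuchal_emg))
    tw <- detect_twitches(rectify_smooth(s$recording$forelimb_emg), bouts)
    truth <- s$truth$twitch_times_s
    hit <- vapply(truth, function(t0) any(abs(tw$times_s - t0) <= 0.025), logical(1))
    c(recall = mean(hit), n_extra = length(tw$times_s), n_truth = length(truth))
  }
  strong <- recovered(3.5, 31)
  expect_gte(strong["recall"], 0.95)
  weak <- recovered(2.0, 31)
  expect_equal(unname(weak["recall"]), 0)
})

test_that("state_rates computes per-bout rates and flags missing tests", {
  bouts <- bout_segmentation(c(0, 60), c(60, 120), c("active_sleep", "wake"))
  ev <- seq(1, 55, length.out = 10)      # 10 events in the 60 s sleep bout
  r <- state_rates(ev, bouts)
  expect_equal(r$by_bout$rate[1], 10)    # events/min
  expect_equal(r$by_bout$rate[2], 0)
  expect_false(r$test_available)         # 1 pair < 20
})

test_that("gated sessions fire more during sleep than wake", {
  wins <- 0L; n <- 60L
  for (sd in seq_len(n)) {
    s <- generate_session(session_config(duration_s = 600, seed = 200 + sd),
                          channels = "spikes")
    r <- state_rates(s$recording$spikes, s$truth$bouts, unit = "hz")
    if (all(c("active_sleep", "wake") %in% names(r$state_means)) &&
        r$state_means["active_sleep"] > r$state_means["wake"]) wins <- wins + 1L
  }
  expect_gte(wins / n, 0.95)
})

test_that("state_rates pairs successive bouts for the Wilcoxon test", {
  set.seed(5)
  on <- seq(0, 39) * 30
  bouts <- bout_segmentation(on, on + 30, rep(c("wake", "active_sleep"), 20))
  ev <- sort(c(runif(300, 0, 1200),                      # uniform background
               unlist(lapply(which(bouts$label == "active_sleep"), function(i)
                 runif(15, bouts$onset_s[i], bouts$offset_s[i])))))
  r <- state_rates(ev, bouts)
  expect_true(r$test_available)
  expect_equal(r$n_pairs, 20L)
  expect_lt(r$wilcoxon$p.value, 0.01)
})
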