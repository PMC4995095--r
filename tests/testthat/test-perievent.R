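mk_corr <- function(rate_hz, window_s, bin_s) {
  nb <- length(rate_hz)
  structure(list(bin_edges_s = (-(nb / 2):(nb / 2)) * bin_s, rate_hz = rate_hz,
                 counts = as.integer(rate_hz), n_triggers = 1L, n_dropped = 0L,
                 spec = correlation_spec(window_s, bin_s),
                 upper_hz = NULL, lower_hz = NULL, alpha = NULL),
            class = "event_correlation")
}

test_that("presets carry the standard window/bin geometries", {
  expect_equal(correlation_preset("ecn_spont")$n_bins, 300L)
  expect_equal(correlation_preset("smc_spont")$n_bins, 40L)
  expect_equal(correlation_preset("stimulation")$n_bins, 50L)
  expect_equal(correlation_preset("infusion")$n_bins, 60L)
  expect_error(correlation_spec(0.3, 0.007), "whole bins")
})

test_that("a lone perievent spike lands in exactly one bin at 1000 Hz", {
  corr <- event_correlation(c(10.0055, 20.0055), c(10, 20),
                            correlation_preset("ecn_spont"), t_range = c(0, 30))
  # dt = 5.5 ms -> the [0.005, 0.006) bin; rate = 2 / (2 x 0.001 s)
  hot <- which(corr$rate_hz > 0)
  expect_equal(length(hot), 1L)
  expect_equal(bin_centers(corr)[hot], 0.0055)
  expect_equal(corr$rate_hz[hot], 1000)
})

test_that("event_correlation equals the brute-force nested loop exactly", {
  set.seed(33)
  for (i in 1:25) {
    n_sp <- sample(0:30, 1); n_tr <- sample(1:8, 1)
    spikes <- sort(runif(n_sp, 0, 20))
    trig <- sort(runif(n_tr, 0, 20))
    spec <- correlation_spec(0.4, 0.05)
    oracle <- brute_force_counts(spikes, trig, spec, c(0, 20))
    if (all(trig - 0.2 < 0 | trig + 0.2 > 20)) {
      expect_error(event_correlation(spikes, trig, spec, t_range = c(0, 20)),
                   "no trigger")
    } else {
      corr <- event_correlation(spikes, trig, spec, t_range = c(0, 20))
      expect_identical(corr$counts, as.integer(oracle))
    }
  }
})

test_that("bin counts sum to the number of in-window pairs", {
  set.seed(44)
  spikes <- sort(runif(500, 0, 100))
  trig <- sort(runif(40, 1, 99))
  spec <- correlation_spec(0.5, 0.01)
  corr <- event_correlation(spikes, trig, spec, t_range = c(0, 100))
  pairs <- sum(vapply(trig, function(t0)
    sum(spikes >= t0 - 0.25 & spikes <= t0 + 0.25), numeric(1)))
  expect_equal(sum(corr$counts), pairs)
  # and with no spikes the histogram is identically zero
  empty <- event_correlation(numeric(), trig, spec, t_range = c(0, 100))
  expect_true(all(empty$rate_hz == 0))
})

test_that("edge triggers are dropped, not padded", {
  spec <- correlation_spec(1, 0.1)
  corr <- event_correlation(c(5), c(0.2, 5, 9.9), spec, t_range = c(0, 10))
  expect_equal(corr$n_triggers, 1L)
  expect_equal(corr$n_dropped, 2L)
})

test_that("jitter surrogates preserve counts and per-cell membership", {
  set.seed(55)
  trig <- sort(runif(50, 0, 100))
  jspec <- jitter_spec(n_surrogates = 300, jitter_window_s = 0.5)
  surr <- jitter_surrogates(trig, jspec, t0_s = 0, seed = 9)
  expect_equal(dim(surr), c(300L, 50L))
  cells <- floor(trig / 0.5)
  for (i in c(1, 150, 300))
    expect_equal(floor(surr[i, ] / 0.5), cells)
})

test_that("jittered times are uniform within their cell", {
  trig <- 10.2                      # cell [10, 10.5)
  surr <- jitter_surrogates(trig, jitter_spec(1000, 0.5), t0_s = 0, seed = 77)
  u <- (as.vector(surr) - 10) / 0.5
  ks <- stats::ks.test(u, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate surrogate ensembles give collapsed bands", {
  obs <- mk_corr(rep(2, 10), 0.1, 0.01)
  b <- acceptance_bands(obs, matrix(2, 1000, 10), alpha = 0.01)
  expect_true(all(b$upper_hz == 2))
  expect_true(all(b$lower_hz == 2))
  expect_false(band_crossings(b)$any)
  expect_error(acceptance_bands(obs, matrix(rnorm(50 * 10), 50, 10), alpha = 0.01),
               "cannot resolve")
})

test_that("an injected evoked response reliably exceeds the upper band", {
  hits <- 0L
  for (sd in 1:5) {
    s <- generate_session(session_config(duration_s = 600, seed = 400 + sd),
                          channels = "spikes")
    corr <- jitter_bands(s$recording$spikes, s$truth$twitch_times_s, "ecn_spont",
                         jitter_spec(1000), t_range = c(0, 600), seed = sd)
    cr <- band_crossings(corr)
    cen <- bin_centers(corr)
    if (length(cr$above) && any(cen[cr$above] > 0 & cen[cr$above] <= 0.06))
      hits <- hits + 1L
  }
  expect_equal(hits, 5L)
})

test_that("peak_rate returns the maximum bin and breaks ties early", {
  corr <- mk_corr(c(0, 0, 0, 0, 0, 5, 2, 0), 0.4, 0.05)
  pk <- peak_rate(corr, c(0, 0.2))
  expect_equal(pk$peak_hz, 5)
  expect_equal(pk$latency_s, 0.075)
  tied <- mk_corr(c(0, 0, 0, 0, 3, 3, 1, 0), 0.4, 0.05)
  expect_equal(peak_rate(tied, c(0, 0.2))$latency_s, 0.025)
  expect_error(peak_rate(corr, c(0.5, 0.6)), "empty")
})

test_that("evoked latency is recovered across seeded sessions", {
  ok <- 0L; n <- 30L
  for (sd in seq_len(n)) {
    s <- generate_session(session_config(duration_s = 600, seed = 600 + sd),
                          channels = "spikes")
    corr <- event_correlation(s$recording$spikes, s$truth$twitch_times_s,
                              "ecn_spont", t_range = c(0, 600))
    lat <- peak_rate(corr)$latency_s
    if (lat > 0.01 && lat <= 0.05) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.95)
})

test_that("waveform_average reduces to exact arithmetic on tiny cases", {
  fs <- 100
  tt <- (0:(20 * fs - 1)) / fs
  sig <- continuous_signal(sin(2 * pi * 1 * tt), fs)      # period 1 s
  spec <- correlation_spec(0.5, 0.25)
  wa <- waveform_average(sig, c(5, 9, 13), spec)          # identical phase
  expect_equal(wa$n_triggers, 3L)
  expect_true(all(wa$sem < 1e-10))
  two <- continuous_signal(c(rep(1, 500), rep(3, 1500)), fs)
  wa2 <- waveform_average(two, c(2.5, 12.5), spec)        # segments of 1s and 3s
  expect_equal(unique(wa2$mean), 2)
  expect_equal(unique(wa2$sem), 1)
})

test_that("waveform average of a random-phase sine vanishes as n grows", {
  set.seed(66)
  fs <- 200
  tt <- (0:(400 * fs - 1)) / fs
  sig <- continuous_signal(sin(2 * pi * 7.3 * tt), fs)
  trig <- sort(runif(200, 1, 399))
  wa <- waveform_average(sig, trig, correlation_spec(0.5, 0.25))
  expect_lt(max(abs(wa$mean)), 3 / sqrt(wa$n_triggers))
})

test_that("stimulation comparison is degenerate-zero for identical states", {
  bouts <- bout_segmentation(c(0, 100), c(100, 200), c("active_sleep", "wake"))
  stims <- c(seq(10, 90, by = 10), seq(110, 190, by = 10))
  # spikes mirrored across states so per-state correlations are
  # identical (offset at a bin center, away from edge ambiguity)
  spikes <- sort(c(stims[1:9] + 0.025, stims[10:18] + 0.025))
  sessions <- lapply(1:3, function(i)
    list(spikes = spikes, stim_times = stims, bouts = bouts, t_range = c(0, 200)))
  res <- stimulation_state_comparison(sessions)
  expect_equal(unname(res$t_test$statistic), 0)
})

test_that("subjects missing stimulations in a state are excluded", {
  bouts <- bout_segmentation(c(0, 100), c(100, 200), c("active_sleep", "wake"))
  good <- list(spikes = sort(runif(200, 0, 200)),
               stim_times = c(seq(10, 90, 10), seq(110, 190, 10)),
               bouts = bouts, t_range = c(0, 200))
  bad <- list(spikes = sort(runif(200, 0, 200)),
              stim_times = seq(10, 90, 10),    # sleep only
              bouts = bouts, t_range = c(0, 200))
  expect_warning(res <- stimulation_state_comparison(list(good, bad, good)),
                 "excluded")
  expect_equal(res$excluded, 2L)
  expect_equal(sort(unique(res$peaks$subject)), c(1L, 3L))
})
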