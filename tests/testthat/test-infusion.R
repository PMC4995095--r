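test_that("epoch_split partitions events with the half-open boundary", {
  des <- infusion_design(c(0, 1800), c(1800, 3600))
  ev <- event_series(c(100, 1799.999, 1800, 3599), t0_s = 0, duration_s = 3600)
  halves <- epoch_split(ev, des)
  expect_equal(halves$pre$times_s, c(100, 1799.999))
  expect_equal(halves$post$times_s, c(1800, 3599))   # boundary event -> post
  expect_equal(halves$pre$duration_s, 1800)
  # 45-minute recording cannot cover both epochs
  short <- event_series(c(100, 2000), t0_s = 0, duration_s = 2700)
  expect_error(epoch_split(short, des), "cover")
})

test_that("epoch_split cuts continuous signals at the right samples", {
  des <- infusion_design(c(0, 10), c(10, 20))
  sig <- continuous_signal(seq_len(200), 10, t0_s = 0)
  halves <- epoch_split(sig, des)
  expect_equal(length(halves$pre$samples), 100L)
  expect_equal(halves$post$t0_s, 10)
  expect_equal(halves$post$samples[1], 101)
})

test_that("baseline subtraction zeroes the quiescence window exactly", {
  # deterministic regular train: one spike in every 50 ms bin of every
  # window -> constant 20 Hz per bin -> exact zeros after subtraction
  spikes <- seq(0.025, 200, by = 0.05)
  trig <- seq(20, 180, by = 10) + 0.0125
  corr <- baseline_subtracted_correlation(spikes, trig, t_range = c(0, 200))
  expect_equal(max(abs(corr$rate_hz)), 0, tolerance = 1e-9)
  expect_equal(corr$quiescence_rate_hz, 20)
})

test_that("baseline subtraction centers homogeneous Poisson spiking at zero", {
  set.seed(17)
  spikes <- sort(runif(5 * 600, 0, 600))
  trig <- sort(runif(60, 5, 595))
  corr <- baseline_subtracted_correlation(spikes, trig, t_range = c(0, 600))
  expect_equal(mean(corr$rate_hz[corr$quiescence_bins]), 0, tolerance = 1e-9)
  se <- stats::sd(corr$rate_hz) / sqrt(corr$spec$n_bins)
  expect_lt(abs(mean(corr$rate_hz)), 3 * se + 0.5)
})

test_that("delta of identical epochs is identically zero", {
  spikes <- sort(runif(1000, 0, 600)); trig <- sort(runif(50, 5, 595))
  a <- baseline_subtracted_correlation(spikes, trig, t_range = c(0, 600))
  d <- delta_correlation(a, a)
  expect_true(all(d$delta_hz == 0))
  b <- event_correlation(spikes, trig, correlation_spec(2, 0.05), t_range = c(0, 600))
  expect_error(delta_correlation(a, b), "specs differ")
})

test_that("peak_change takes the signed extremum, earliest on ties", {
  mk_delta <- function(v, bin = 0.05) {
    nb <- length(v)
    structure(list(bin_edges_s = (-(nb / 2):(nb / 2)) * bin, delta_hz = v,
                   spec = correlation_spec(nb * bin, bin)),
              class = "delta_correlation")
  }
  expect_equal(peak_change(mk_delta(rep(0, 8)), c(0, 0.2))$peak_change_hz, 0)
  d <- mk_delta(c(0, 0, 0, 0, 0, 2, -1, 0))
  pk <- peak_change(d, c(0, 0.2))
  expect_equal(pk$peak_change_hz, 2)
  expect_equal(pk$latency_s, 0.075)
  neg <- mk_delta(c(0, 0, 0, 0, 1, -3, 0, 0))
  expect_equal(peak_change(neg, c(0, 0.2))$peak_change_hz, -3)
  expect_error(peak_change(d, c(5, 6)), "empty")
})

test_that("compare_conditions is zero for identical groups and flags small ones", {
  df <- data.frame(group = rep(c("drug", "saline"), each = 4),
                   pre = rep(c(4, 5, 6, 7), 2), post = rep(c(5, 6, 7, 8), 2))
  res <- compare_conditions(df)
  expect_true(res$available)
  expect_equal(unname(res$between$statistic), 0)
  tiny <- data.frame(group = c("drug", "saline"), pre = c(1, 1), post = c(2, 2))
  expect_false(compare_conditions(tiny)$available)
})

test_that("motor_metrics computes per-minute rates and percent differences", {
  pre <- list(movements = interval_series(seq(10, 1750, by = 60),
                                          seq(10, 1750, by = 60) + 0.5),
              twitches = seq(1, 1799, length.out = 90),
              spikes = seq(0.1, 1799, length.out = 9000))
  post <- list(movements = interval_series(seq(10, 1750, by = 40),
                                           seq(10, 1750, by = 40) + 0.5),
               twitches = seq(1, 1799, length.out = 90),
               spikes = seq(0.1, 1799, length.out = 9000))
  m <- motor_metrics(pre, post, 1800, 1800)
  expect_equal(m$pre[m$metric == "wake_movements_per_min"], 1)
  # uniform spiking: masking perievent windows leaves the rate unchanged
  expect_equal(m$pre[m$metric == "tonic_rate_hz"], 5, tolerance = 0.02)
  expect_equal(m$pct_diff[m$metric == "twitches_per_min"], 0)
  # pre 10/min vs post 15/min -> +50%
  m2 <- motor_metrics(list(twitches = seq(1, 299, length.out = 50)),
                      list(twitches = seq(1, 299, length.out = 75)),
                      300, 300)
  expect_equal(m2$pct_diff[m2$metric == "twitches_per_min"], 50)
  # zero pre metric -> undefined percent difference
  m3 <- motor_metrics(list(), list(twitches = 1:3), 300, 300)
  expect_true(is.na(m3$pct_diff[m3$metric == "twitches_per_min"]))
})

test_that("drug infusions unmask the wake response; saline ones do not", {
  # short epochs keep this fast; the acceptance suite runs the full design
  des <- function(g) infusion_design(c(0, 600), c(600, 1200), group = g,
                                     expected_latency_window_s = c(0, 0.2))
  delta_peaks <- function(group, sd) {
    cfg <- session_config(duration_s = 600, seed = sd)
    inf <- generate_infusion_session(cfg, des(group))
    res <- infusion_delta_analysis(inf)
    c(wake = res$peak$wake$peak_change_hz,
      sleep = res$peak$active_sleep$peak_change_hz)
  }
  drug <- t(vapply(1:5, function(sd) delta_peaks("drug", 700 + sd), numeric(2)))
  saline <- t(vapply(1:5, function(sd) delta_peaks("saline", 700 + sd), numeric(2)))
  # sign of the group difference in wake recovered
  expect_gt(mean(drug[, "wake"]), mean(saline[, "wake"]) + 5)
  # sleep deltas are null in both groups relative to the wake unmasking
  expect_lt(abs(mean(drug[, "sleep"])), abs(mean(drug[, "wake"])) / 2)
})
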