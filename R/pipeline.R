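# Pipeline orchestration: the experiment templates as one entry point.

#' Run a pipeline stage
#'
#' Ties the stages together under a single configuration and seed.  All
#' randomness flows from `config$seed`; rerunning a command with the
#' same configuration produces byte-identical outputs, and every output
#' embeds the configuration hash.
#'
#' Commands:
#' * `simulate` — generate a synthetic session; writes the signal
#'   container (`session/`) and ground-truth tables (`truth_bouts.csv`,
#'   `truth_twitches.csv`, `truth_wake_movements.csv`,
#'   `truth_spindles.csv`).
#' * `score` — score tone and extract motor events from the session
#'   container; writes `bouts.csv`, `twitches.csv`, `wake_movements.csv`.
#' * `spindles` — detect spindle bursts in the LFP; writes
#'   `spindles.csv`.
#' * `perievent` — twitch-triggered correlation of the spike train with
#'   jitter acceptance bands; writes `correlation.json`.
#' * `infusion` — simulate a pre/post infusion pair and run the
#'   delta-rate analysis; writes `delta.json`.
#' * `report` — collect the artifacts of previous stages into
#'   `report.json`.
#'
#' @param config a [pipeline_config()].
#' @param command stage to run.
#' @param out_dir output directory (created if needed); stages read the
#'   artifacts earlier stages wrote there.
#' @return the stage's main result, invisibly.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "score", "spindles",
                                     "perievent", "infusion", "report"),
                         out_dir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  command <- match.arg(command)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, ...)
  stamp <- function(x) c(list(config_hash = config$hash, seed = config$seed), x)
  write_json_out <- function(x, file)
    jsonlite::write_json(stamp(x), path(file), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)

  if (command == "simulate") {
    sess <- generate_session(config$session)
    write_signals(sess$recording, path("session"), config_hash = config$hash)
    write_events(event_series(sess$truth$twitch_times_s, "twitch"),
                 path("truth_twitches.csv"))
    write_events(sess$truth$bouts, path("truth_bouts.csv"))
    write_events(sess$truth$wake_move_intervals, path("truth_wake_movements.csv"))
    write_events(sess$truth$spindle_intervals, path("truth_spindles.csv"))
    return(invisible(sess))
  }

  if (command == "score") {
    rec <- read_signals(path("session"))
    nuc <- rectify_smooth(rec$nuchal_emg)
    limb <- rectify_smooth(rec$forelimb_emg)
    bouts <- score_tone(nuc, config$scoring)
    tw <- detect_twitches(limb, bouts, config$scoring)
    mv <- detect_wake_movements(limb, bouts, config$scoring)
    write_events(bouts, path("bouts.csv"))
    write_events(tw, path("twitches.csv"))
    write_events(mv, path("wake_movements.csv"))
    return(invisible(list(bouts = bouts, twitches = tw, movements = mv)))
  }

  if (command == "spindles") {
    rec <- read_signals(path("session"))
    sp <- detect_spindles(rec$lfp, config$spindle)
    utils::write.csv(as.data.frame(sp), path("spindles.csv"), row.names = FALSE)
    return(invisible(sp))
  }

  if (command == "perievent") {
    rec <- read_signals(path("session"))
    tw <- read_events(path("twitches.csv"))
    corr <- jitter_bands(rec$spikes, tw, correlation_preset("ecn_spont"),
                         config$jitter, seed = config$seed + 11L)
    cr <- band_crossings(corr)
    write_json_out(list(
      preset = corr$spec$name, bin_edges_s = corr$bin_edges_s,
      rate_hz = corr$rate_hz, upper_hz = corr$upper_hz, lower_hz = corr$lower_hz,
      alpha = corr$alpha, n_triggers = corr$n_triggers,
      bins_above_band = cr$above), "correlation.json")
    return(invisible(corr))
  }

  if (command == "infusion") {
    inf <- generate_infusion_session(config$session, config$infusion)
    res <- infusion_delta_analysis(inf)
    write_json_out(list(
      group = config$infusion$group,
      state = names(res$delta),
      delta_hz = lapply(res$delta, function(d) d$delta_hz),
      peak_change_hz = lapply(res$peak, function(p) p$peak_change_hz),
      latency_window_s = res$latency_window,
      motor_metrics = res$motor), "delta.json")
    return(invisible(res))
  }

  if (command == "report") {
    files <- c("bouts.csv", "twitches.csv", "wake_movements.csv", "spindles.csv",
               "correlation.json", "delta.json")
    present <- files[file.exists(path(files))]
    write_json_out(list(artifacts = present), "report.json")
    return(invisible(present))
  }
}

#' Delta-rate analysis of one infusion session
#'
#' Runs the full pre/post analysis on a simulated (or assembled)
#' infusion session: per-state baseline-subtracted correlations for each
#' epoch, post-minus-pre deltas, the expected-latency window from the
#' pooled raw correlation with jitter bands, peak changes, and the
#' motor-metric table.
#'
#' @param inf an `infusion_session` from [generate_infusion_session()],
#'   or a list with the same `pre`/`post`/`design` shape.
#' @param jspec a [jitter_spec()] for the pooled-correlation bands.
#' @param seed seed for the surrogate draw.
#' @return list with `delta` (per state: [delta_correlation()]), `peak`
#'   (per state: [peak_change()]), `latency_window` (per state), `motor`
#'   (data.frame), `pre_corr`, `post_corr`.
#' @export
infusion_delta_analysis <- function(inf, jspec = jitter_spec(), seed = 1L) {
  design <- inf$design
  spec <- correlation_preset("infusion")
  epochs <- list(pre = inf$pre, post = inf$post)
  triggers <- function(sess, state) {
    if (state == "wake") sess$truth$wake_move_intervals$onset_s
    else sess$truth$twitch_times_s
  }
  t_range <- function(sess) {
    c(sess$truth$bouts$onset_s[1L], sess$truth$bouts$offset_s[nrow(sess$truth$bouts)])
  }
  states <- c(wake = "wake", active_sleep = "active_sleep")
  out <- list(delta = list(), peak = list(), latency_window = list(),
              pre_corr = list(), post_corr = list())
  for (state in states) {
    corr <- lapply(epochs, function(ep)
      baseline_subtracted_correlation(ep$recording$spikes, triggers(ep, state),
                                      spec, design, t_range = t_range(ep)))
    delta <- delta_correlation(corr$post, corr$pre)
    # expected latency from the pooled raw correlation across both epochs
    all_spikes <- sort(c(inf$pre$recording$spikes$times_s,
                         inf$post$recording$spikes$times_s))
    all_trig <- sort(c(triggers(inf$pre, state), triggers(inf$post, state)))
    lw <- design$expected_latency_window_s
    if (is.null(lw)) {
      pooled <- jitter_bands(all_spikes, all_trig, spec, jspec,
                             t_range = c(0, design$post_interval[2L]), seed = seed)
      lw <- suppressWarnings(expected_latency_window(pooled))
    }
    out$delta[[state]] <- delta
    out$peak[[state]] <- peak_change(delta, lw)
    out$latency_window[[state]] <- lw
    out$pre_corr[[state]] <- corr$pre
    out$post_corr[[state]] <- corr$post
  }
  out$motor <- motor_metrics(
    pre = list(movements = inf$pre$truth$wake_move_intervals,
               twitches = inf$pre$truth$twitch_times_s,
               spikes = inf$pre$recording$spikes),
    post = list(movements = inf$post$truth$wake_move_intervals,
                twitches = inf$post$truth$twitch_times_s,
                spikes = inf$post$recording$spikes),
    pre_dur_s = diff(design$pre_interval), post_dur_s = diff(design$post_interval))
  out
}
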