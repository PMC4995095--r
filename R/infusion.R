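# Pre/post-infusion delta-firing-rate analysis.

#' Infusion experiment design
#'
#' Pre- and post-infusion epochs (default 30 min each), experimental
#' group, and the quiescence window used for baseline subtraction
#' (1-1.5 s before the trigger).
#'
#' @param pre_interval,post_interval `c(start, end)` seconds; disjoint,
#'   default `c(0, 1800)` and `c(1800, 3600)`.
#' @param group `"drug"` or `"saline"`.
#' @param quiescence_window_s window relative to the trigger whose mean
#'   rate is subtracted, default `c(-1.5, -1.0)`.
#' @param expected_latency_window_s optional `c(lo, hi)` seconds: where
#'   to search for the peak change; when `NULL` it is derived from the
#'   pooled raw correlations (see [expected_latency_window()]).
#' @return list of class `infusion_design`.
#' @export
infusion_design <- function(pre_interval = c(0, 1800),
                            post_interval = c(1800, 3600),
                            group = c("drug", "saline"),
                            quiescence_window_s = c(-1.5, -1.0),
                            expected_latency_window_s = NULL) {
  group <- match.arg(group)
  if (length(pre_interval) != 2L || length(post_interval) != 2L ||
      diff(pre_interval) <= 0 || diff(post_interval) <= 0)
    stop("infusion_design: intervals must be increasing pairs")
  if (pre_interval[2L] > post_interval[1L])
    stop("infusion_design: pre and post intervals must be disjoint (pre before post)")
  if (quiescence_window_s[2L] > 0)
    stop("infusion_design: quiescence window must precede the trigger")
  structure(list(pre_interval = pre_interval, post_interval = post_interval,
                 group = group, quiescence_window_s = quiescence_window_s,
                 expected_latency_window_s = expected_latency_window_s),
            class = "infusion_design")
}

#' Split a recording into pre- and post-infusion views
#'
#' Event series are partitioned by time with the half-open convention
#' (an event exactly at the epoch boundary belongs to the post epoch);
#' continuous signals are cut at the corresponding samples.  Lists are
#' split element-wise.  The recording must cover both epochs.
#'
#' @param x an [event_series()], [continuous_signal()],
#'   [interval_series()], or a (possibly nested) list of them.
#' @param design an [infusion_design()].
#' @return list with elements `pre` and `post`, the same shape as `x`.
#' @export
epoch_split <- function(x, design = infusion_design()) {
  stopifnot(inherits(design, "infusion_design"))
  span_end <- design$post_interval[2L]
  cut1 <- function(obj, iv) {
    if (inherits(obj, "continuous_signal")) {
      if (obj$t0_s > design$pre_interval[1L] ||
          obj$t0_s + signal_duration(obj) < span_end - 1e-9)
        stop("epoch_split: recording does not cover both epochs")
      i0 <- floor((iv[1L] - obj$t0_s) * obj$rate_hz) + 1L
      i1 <- floor((iv[2L] - obj$t0_s) * obj$rate_hz)
      continuous_signal(obj$samples[i0:min(i1, length(obj$samples))], obj$rate_hz,
                        t0_s = iv[1L], label = obj$label, units = obj$units)
    } else if (inherits(obj, "event_series")) {
      if (!is.na(obj$duration_s) &&
          (obj$t0_s > design$pre_interval[1L] || obj$t0_s + obj$duration_s < span_end - 1e-9))
        stop("epoch_split: recording does not cover both epochs")
      keep <- obj$times_s >= iv[1L] & obj$times_s < iv[2L]
      event_series(obj$times_s[keep], obj$label, t0_s = iv[1L],
                   duration_s = diff(iv))
    } else if (inherits(obj, "interval_series")) {
      keep <- obj$onset_s >= iv[1L] & obj$onset_s < iv[2L]
      out <- obj[keep, , drop = FALSE]
      interval_series(out$onset_s, pmin(out$offset_s, iv[2L]), out$label)
    } else if (is.list(obj)) {
      lapply(obj, cut1, iv = iv)
    } else stop("epoch_split: unsupported object")
  }
  list(pre = cut1(x, design$pre_interval), post = cut1(x, design$post_interval))
}

#' Quiescence-baseline-subtracted perievent correlation
#'
#' Builds the perievent correlation (infusion preset: 3-s window, 50-ms
#' bins, so the window spans the -1.5 to -1.0 s quiescence period) and
#' subtracts the mean rate over the quiescence bins (bins whose centers
#' lie in the quiescence window) from every bin, so the quiescence-window
#' mean of the result is zero by construction.
#'
#' @inheritParams event_correlation
#' @param design an [infusion_design()].
#' @return an `event_correlation` with extra fields
#'   `quiescence_rate_hz` and `quiescence_bins`.
#' @export
baseline_subtracted_correlation <- function(spikes, triggers,
                                            spec = correlation_preset("infusion"),
                                            design = infusion_design(),
                                            t_range = NULL) {
  if (is.character(spec)) spec <- correlation_preset(spec)
  qw <- design$quiescence_window_s
  if (qw[1L] < -spec$window_s / 2)
    stop("baseline_subtracted_correlation: quiescence window outside the correlation window")
  corr <- event_correlation(spikes, triggers, spec, t_range)
  cen <- bin_centers(corr)
  qbins <- which(cen >= qw[1L] & cen < qw[2L])
  if (!length(qbins))
    stop("baseline_subtracted_correlation: no bins in the quiescence window")
  base <- mean(corr$rate_hz[qbins])
  corr$rate_hz <- corr$rate_hz - base
  corr$quiescence_rate_hz <- base
  corr$quiescence_bins <- qbins
  corr
}

#' Post-minus-pre delta correlation
#'
#' Per-bin difference of two correlations computed with the same spec
#' (normally both baseline-subtracted): the change in perievent firing
#' rate between the post- and pre-infusion epochs.
#'
#' @param post_corr,pre_corr [event_correlation()]s with identical specs.
#' @return object of class `delta_correlation`: `bin_edges_s`,
#'   `delta_hz`, `spec`, `n_triggers` (pre/post).
#' @export
delta_correlation <- function(post_corr, pre_corr) {
  stopifnot(inherits(post_corr, "event_correlation"),
            inherits(pre_corr, "event_correlation"))
  if (!identical(post_corr$spec[c("window_s", "bin_s")],
                 pre_corr$spec[c("window_s", "bin_s")]))
    stop("delta_correlation: correlation specs differ")
  structure(list(bin_edges_s = post_corr$bin_edges_s,
                 delta_hz = post_corr$rate_hz - pre_corr$rate_hz,
                 spec = post_corr$spec,
                 n_triggers = c(pre = pre_corr$n_triggers, post = post_corr$n_triggers)),
            class = "delta_correlation")
}

#' Group-average delta correlation
#'
#' Averages per-subject delta correlations within an experimental group,
#' with the standard error across subjects for every bin.
#'
#' @param deltas list of [delta_correlation()]s (one per subject).
#' @return object of class `delta_group`: `bin_edges_s`, `mean_hz`,
#'   `sem_hz`, `n_subjects`, `spec`.
#' @export
group_delta <- function(deltas) {
  stopifnot(length(deltas) >= 1L)
  D <- do.call(rbind, lapply(deltas, function(d) d$delta_hz))
  structure(list(bin_edges_s = deltas[[1L]]$bin_edges_s,
                 mean_hz = colMeans(D),
                 sem_hz = if (nrow(D) > 1L) apply(D, 2L, stats::sd) / sqrt(nrow(D))
                          else rep(0, ncol(D)),
                 n_subjects = nrow(D), spec = deltas[[1L]]$spec),
            class = "delta_group")
}

#' Expected-latency window from a pooled raw correlation
#'
#' The paper-style rule: the window of expected sensory reafference is
#' the contiguous run of bins that exceed the jitter upper band in the
#' pooled raw (not baseline-subtracted) correlation.  Falls back to the
#' post-trigger half-window, with a warning, when no bin crosses.
#'
#' @param pooled_corr an [event_correlation()] with bands
#'   (e.g. from [jitter_bands()] on pooled data).
#' @return `c(lo, hi)` seconds.
#' @export
expected_latency_window <- function(pooled_corr) {
  cr <- band_crossings(pooled_corr)
  if (!length(cr$above)) {
    warning("expected_latency_window: no bin exceeds the upper band; using the post-trigger half-window")
    return(c(0, pooled_corr$spec$window_s / 2))
  }
  cen <- bin_centers(pooled_corr)
  # contiguous run containing the largest exceedance
  i0 <- cr$above[which.max(pooled_corr$rate_hz[cr$above] -
                             pooled_corr$upper_hz[cr$above])]
  run <- i0
  while ((min(run) - 1L) %in% cr$above) run <- c(min(run) - 1L, run)
  while ((max(run) + 1L) %in% cr$above) run <- c(run, max(run) + 1L)
  half_bin <- pooled_corr$spec$bin_s / 2
  c(cen[min(run)] - half_bin, cen[max(run)] + half_bin)
}

#' Peak change in firing rate within the expected-latency window
#'
#' The signed value of largest magnitude of the delta correlation within
#' the window; ties return the earliest bin.
#'
#' @param delta a [delta_correlation()] or [group_delta()].
#' @param window_s `c(lo, hi)` seconds relative to the trigger.
#' @return list with `peak_change_hz` and `latency_s`.
#' @export
peak_change <- function(delta, window_s) {
  v <- if (inherits(delta, "delta_group")) delta$mean_hz else delta$delta_hz
  e <- delta$bin_edges_s
  cen <- (e[-1L] + e[-length(e)]) / 2
  sel <- which(cen >= window_s[1L] & cen <= window_s[2L])
  if (!length(sel)) stop("peak_change: empty window")
  i <- sel[which.max(abs(v[sel]))]
  list(peak_change_hz = v[i], latency_s = cen[i])
}

#' Compare drug and saline conditions
#'
#' Within each group, a paired t test of post vs pre; between groups, an
#' independent-sample t test on the percent differences
#' `100 * (post - pre) / pre` (and, when `peak_change` columns are
#' supplied, on the peak changes themselves).
#'
#' @param df data.frame with columns `group` (`"drug"`/`"saline"`),
#'   `pre`, `post` (one row per subject); optionally `peak_change`.
#' @return list of class `condition_comparison`: `within` (per-group
#'   paired `htest` or `NULL`), `between` (`htest` on percent
#'   differences), `between_peak` (optional), `table`, `available`.
#' @export
compare_conditions <- function(df) {
  stopifnot(all(c("group", "pre", "post") %in% names(df)))
  df$pct_diff <- ifelse(df$pre == 0, NA_real_, 100 * (df$post - df$pre) / df$pre)
  groups <- split(df, df$group)
  ok <- all(vapply(groups, nrow, integer(1)) >= 2L) && length(groups) == 2L
  within <- lapply(groups, function(g) {
    if (nrow(g) >= 2L && stats::sd(g$post - g$pre) > 0)
      stats::t.test(g$post, g$pre, paired = TRUE) else NULL
  })
  between <- NULL; between_peak <- NULL
  if (ok) {
    a <- groups[[1L]]$pct_diff; b <- groups[[2L]]$pct_diff
    if (sum(!is.na(a)) >= 2L && sum(!is.na(b)) >= 2L && stats::sd(c(a, b), na.rm = TRUE) > 0)
      between <- stats::t.test(a, b, var.equal = FALSE)
    if ("peak_change" %in% names(df)) {
      pa <- groups[[1L]]$peak_change; pb <- groups[[2L]]$peak_change
      if (stats::sd(c(pa, pb)) > 0) between_peak <- stats::t.test(pa, pb, var.equal = FALSE)
      else between_peak <- list(statistic = c(t = 0), p.value = 1)
    }
  }
  structure(list(within = within, between = between, between_peak = between_peak,
                 table = df, available = ok),
            class = "condition_comparison")
}

#' Motor metrics across the pre/post epochs
#'
#' Frequencies of wake movements and twitches (events/min) and the tonic
#' firing rate (Hz) in each epoch, with percent differences
#' `100 * (post - pre) / pre` (undefined, flagged `NA`, when the pre
#' metric is zero).  Tonic rate is background firing: spikes inside a
#' perievent exclusion window around every movement onset and twitch
#' (default 0.1 s before to 0.5 s after) are removed, and the remaining
#' count is divided by the unmasked time, so evoked responses do not
#' masquerade as a change in ongoing activity.
#'
#' @param pre,post named lists with elements `movements`
#'   ([interval_series()] or numeric onsets), `twitches`, `spikes`
#'   ([event_series()] or numeric).
#' @param pre_dur_s,post_dur_s epoch durations, seconds.
#' @param exclude_s perievent exclusion window `c(before, after)` for
#'   the tonic rate, seconds.
#' @return data.frame with columns `metric`, `pre`, `post`, `pct_diff`.
#' @export
motor_metrics <- function(pre, post, pre_dur_s, post_dur_s,
                          exclude_s = c(0.1, 0.5)) {
  times1 <- function(x) {
    if (is.null(x)) numeric()
    else if (inherits(x, "interval_series")) x$onset_s
    else if (inherits(x, "event_series")) x$times_s
    else as.numeric(x)
  }
  tonic <- function(ep, dur) {
    sp <- times1(ep$spikes)
    ev <- sort(c(times1(ep$movements), times1(ep$twitches)))
    if (!length(ev)) return(length(sp) / dur)
    on <- ev - exclude_s[1L]; off <- ev + exclude_s[2L]
    # merge overlapping exclusion windows
    keep <- c(TRUE, on[-1L] > cummax(off[-length(off)]))
    grp <- cumsum(keep)
    on <- tapply(on, grp, min); off <- tapply(off, grp, max)
    masked_t <- sum(off - on)
    masked_n <- sum(vapply(seq_along(on), function(i)
      sum(sp >= on[i] & sp < off[i]), numeric(1)))
    (length(sp) - masked_n) / max(dur - masked_t, 1e-9)
  }
  rows <- data.frame(
    metric = c("wake_movements_per_min", "twitches_per_min", "tonic_rate_hz"),
    pre = c(length(times1(pre$movements)) / pre_dur_s * 60,
            length(times1(pre$twitches)) / pre_dur_s * 60,
            tonic(pre, pre_dur_s)),
    post = c(length(times1(post$movements)) / post_dur_s * 60,
             length(times1(post$twitches)) / post_dur_s * 60,
             tonic(post, post_dur_s)))
  rows$pct_diff <- ifelse(rows$pre == 0, NA_real_,
                          100 * (rows$post - rows$pre) / rows$pre)
  rows
}

#' @export
print.delta_correlation <- function(x, ...) {
  cat(sprintf("<delta_correlation> %d bins; peak |delta| = %.3f Hz\n",
              x$spec$n_bins, max(abs(x$delta_hz))))
  invisible(x)
}

#' @export
print.delta_group <- function(x, ...) {
  cat(sprintf("<delta_group> %d subjects, %d bins; peak |mean delta| = %.3f Hz\n",
              x$n_subjects, x$spec$n_bins, max(abs(x$mean_hz))))
  invisible(x)
}

#' @export
plot.delta_group <- function(x, ...) {
  e <- x$bin_edges_s; cen <- (e[-1L] + e[-length(e)]) / 2
  graphics::plot(cen, x$mean_hz, type = "s", xlab = "time from trigger (s)",
                 ylab = expression(Delta * " rate (Hz)"), ...)
  graphics::lines(cen, x$mean_hz + x$sem_hz, lty = 3)
  graphics::lines(cen, x$mean_hz - x$sem_hz, lty = 3)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}
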