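---
title: "Methods: state-dependent sensory gating analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent sensory gating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

In week-old rodents, self-generated movements come in two kinds with
opposite sensory consequences. Wake movements — high-amplitude,
coordinated limb movements against high nuchal muscle tone — trigger
little reafferent activity in somatosensory structures: a corollary
discharge of the motor command gates the expected reafference. Myoclonic
twitches — brief limb jerks against the muscle atonia of active (REM)
sleep — are not gated: they reliably trigger robust reafference in
brainstem sensory nuclei and sensorimotor cortex. Pharmacological
disinhibition of a brainstem comparator releases the gate: after
infusion of GABA~A~/glycine antagonists, wake movements start to evoke
responses while twitch responses are unchanged.

`twitchgate` implements the complete analysis chain this kind of
experiment needs, as a reusable, tested pipeline:

1. **Preprocessing** — zero-phase band-pass filtering, RMS and
   rectify-and-smooth envelopes, threshold spike extraction
   (`bandpass()`, `rms_envelope()`, `rectify_smooth()`,
   `extract_spikes()`).
2. **State scoring** — dichotomization of the nuchal-EMG envelope into
   wake (high tone) and active sleep (atonia), twitch detection by the
   3x-baseline amplitude rule, wake-movement detection by the midpoint
   threshold and 300-ms duration rule (`score_tone()`,
   `detect_twitches()`, `detect_wake_movements()`, `state_rates()`).
3. **Spindle-burst detection** — RMS thresholding of the 1–40 Hz LFP
   with the criteria: at least three oscillations, dominant frequency
   10–15 Hz, duration at least 100 ms (`detect_spindles()`).
4. **Perievent statistics** — event correlations and waveform averages
   around triggers, interval-jitter surrogates, and simultaneous
   acceptance bands (`event_correlation()`, `jitter_bands()`,
   `waveform_average()`, `stimulation_state_comparison()`).
5. **Infusion Δ-rate analysis** — pre/post epoch splitting, quiescence
   baseline subtraction, post-minus-pre Δ correlations, peak-change
   extraction and drug-vs-saline comparison, with motor-metric controls
   (`epoch_split()`, `baseline_subtracted_correlation()`,
   `delta_correlation()`, `compare_conditions()`, `motor_metrics()`).
6. **Synthetic sessions** — a generator with full ground truth
   (`generate_session()`, `generate_infusion_session()`) so every stage
   can be validated against known inputs.

Because no public recordings exist for this preparation, the package's
validation is property-based: the generator injects known structure and
the analysis must recover it at stated fidelity.

# The synthetic session generator

## What it emulates

A session is a continuous recording of duration `duration_s` containing:

* **Bouts.** Alternating wake / active-sleep bouts. Durations are drawn
  from shifted exponentials: a 10 s floor plus an exponential with the
  remaining mean (`bout_mean_wake_s` = 60 s, `bout_mean_sleep_s` = 90 s
  by default). The floor matches the observation that neonatal
  sleep–wake bouts are not arbitrarily brief; the exponential tail is
  the simplest defensible bout model, since no quantitative
  bout-duration distribution is available for this preparation. These
  defaults are exposed in the configuration rather than asserted as
  faithful.
* **Twitches** as point events at `twitch_rate_hz` (default 0.3 events/s)
  only inside active-sleep bouts, with a 0.5 s margin from bout edges
  and a 0.25 s minimum separation.
* **Wake movements** as intervals inside wake bouts at
  `wake_move_rate_hz` (default 0.08 events/s), duration 0.3 s plus an
  exponential tail (mean `wake_move_dur_s` = 0.5 s).
* **EMG envelopes**, synthesized directly in rectified-envelope space:
  baseline 1 during atonia; the nuchal channel rises to
  `emg_tone_gain` = 5 during wake while limb channels rise only to
  `emg_limb_tone_gain` = 1.5 (limb muscles are largely quiet between
  movements even when nuchal tone is high — this separation is what
  makes nuchal tone the state signal and limb EMG the event signal).
  Twitches are 100 ms raised-cosine bumps peaking at
  `twitch_amp_gain` x baseline. The bump width is chosen so that the
  analysis-side 10 ms envelope smoothing attenuates the peak by less
  than 5%; a substantially narrower transient would smear through the
  smoother and make the 3x amplitude criterion ambiguous near
  threshold. Movements are plateaus at `wake_move_amp_gain` = 6 x
  baseline with 20 ms ramps. Gaussian envelope noise
  (`emg_noise_sd` = 0.05 of baseline) is added and clamped at zero.
* **LFP**: 1/f-shaped Gaussian noise (spectral amplitude proportional to
  `1/sqrt(max(f, 1))`, rescaled to `noise_sd`) plus spindle bursts —
  sinusoids at `spindle_freq_hz` = 12 Hz under a plateau envelope with
  50 ms raised-cosine ramps, peak amplitude `spindle_snr` x `noise_sd`,
  duration `spindle_dur_s` = 0.5 s, only inside active-sleep bouts. The
  plateau (rather than a fully tapered) envelope means a burst that
  satisfies the duration criterion also spends essentially its whole
  extent above an RMS detection threshold, so the oscillation-count
  criterion is evaluated on the burst, not on its tip. Note that the
  criteria themselves make bursts shorter than about 3 cycles
  (250 ms at 12 Hz) undetectable regardless of amplitude.
* **Spikes**: an inhomogeneous Poisson train — homogeneous background at
  `spike_background_hz` = 5 Hz plus, for each trigger of each class, a
  Gaussian rate kernel `amplitude * exp(-(lag - latency)^2 / (2 width^2))`
  with `evoked_latency_s` = 0.02 s, `evoked_kernel_width_s` = 0.01 s and
  peak `evoked_rate_hz` = 100 Hz. The defaults describe a brainstem-like
  response (latency inside the 10–50 ms range; about 2.5 evoked spikes
  per twitch); a cortex-like response is obtained by setting the latency
  near 0.11 s. Sampling is exact, not thinned: each trigger contributes
  `Poisson(amplitude * width * sqrt(2*pi))` spikes at
  `Normal(trigger + latency, width)` times, and a superposition of
  Poisson processes is itself the target inhomogeneous process.
* **Gating**: when `gate_wake = TRUE` and `infusion_post = FALSE`, the
  wake-movement kernel amplitude is zero — movements happen but evoke
  nothing. `infusion_post = TRUE` restores the amplitude (the drug
  condition); stimulation kernels are state-independent throughout.

Every channel draws from its own RNG stream derived from the master
seed by a fixed offset, so sessions are bit-reproducible and channels
can be regenerated independently.

## What it does not emulate

No biophysics: EMG is an envelope, not a waveform; spikes are points,
not extracellular voltages; the LFP noise is stationary 1/f, without
state-dependent spectral changes, movement artifacts, or electrode
drift. Twitches are independent events, not bursts; real twitching is
clustered. The infusion is a binary flag, with no pharmacokinetics.
Consequently, passing tests demonstrate that the analysis recovers the
statistical structure it targets — they do not demonstrate robustness
to artifact classes the generator never produces, which on real data
are handled by the optional exclusion-interval input.

# Detector definitions and their free choices

Several quantities the detection criteria refer to are not fully
specified by the criteria themselves; the package fixes them as
follows, and exposes each in configuration.

**Tone threshold.** The nuchal envelope distribution is split by
two-means clustering (initialized at the envelope extremes) and the
threshold is the midpoint of the two centers; a quantile fallback
(midpoint of the 10th and 90th percentiles) is available. If the two
centers differ by less than 20% the segmentation is declared degenerate
and a single wake bout is returned with a warning. Runs shorter than
`min_bout_s` = 5 s are absorbed into their neighbors, shortest first.

**Twitch baseline.** "Baseline" EMG is the median envelope over
atonia samples — the median is robust to the twitch excursions
themselves. The amplitude criterion is strict (`> 3x`, so a tie at
exactly 3x is not a twitch), the event time is the excursion peak
(onset is a configurable alternative), and a 100 ms refractory period
merges double crossings.

**Movement threshold.** Candidate movements are excursions above the
twitch threshold that start in wake and last at least 300 ms. The
final threshold is the midpoint between the atonia baseline and the
mean peak of the `n_reference_movements` = 5 largest candidates —
largest rather than randomly chosen, for reproducibility. When fewer
than five (but at least one) candidates exist the available ones are
used with a warning; with none, the twitch threshold is used with a
warning.

**Spindle threshold.** Candidate bursts are RMS-envelope excursions
above twice the median envelope; the threshold is the midpoint between
the baseline (median envelope outside candidates — the criteria leave
"baseline" undefined, and the median of quiet data is its natural
robust estimate) and the mean peak RMS of the five largest candidates.
Adjacent excursions separated by less than 50 ms are merged. A burst
is accepted iff duration >= 0.1 s, dominant frequency in 10–15 Hz, and
oscillation count >= 3, where the oscillation count is the number of
zero-crossing pairs of the band-filtered segment and the dominant
frequency is the Hann-windowed periodogram peak, zero-padded to at
least 1 Hz resolution (short bursts need the padding for the 10–15 Hz
bound to be decidable).

All thresholds are relative (multiples of medians or midpoints of
measured levels), which makes every detector invariant to global
amplitude scaling — a property the test suite asserts.

# Perievent statistics

## Correlations

`event_correlation()` histograms spike lags relative to triggers into
bins of a `correlation_spec`; the standard geometries are available as
presets: 1000 ms/25 ms (cortical spontaneous), 300 ms/1 ms (brainstem
spontaneous), 500 ms/10 ms (stimulation), 3000 ms/50 ms (infusion).
Rates are `count / (n_triggers * bin_s)`. Conventions, fixed once and
asserted at boundaries: times are seconds from recording start;
intervals and bins are half-open `[left, right)` with the right edge
inclusive at the window end; triggers whose window does not fit inside
the recording are dropped, not padded; ties in peak searches return
the earliest bin. The binning fast path is verified against a
brute-force nested loop over (trigger, spike) pairs — exact integer
equality on random instances.

## Interval jitter and simultaneous bands

Surrogate trigger sets resample each trigger uniformly within its own
cell of a fixed 500 ms partition anchored at the recording start
(anchoring is otherwise arbitrary; fixing it makes runs reproducible).
Surrogates preserve trigger counts and per-cell occupancy exactly,
destroying structure finer than the cell while preserving coarse rate
co-modulation. Triggers are jittered, not spikes.

The acceptance bands are calibrated on max/min statistics: with `M`
surrogates and `m = floor(alpha/2 * (M+1))`, the upper band is the
m-th largest of the surrogate *maxima over bins* and the lower band
the m-th smallest of the surrogate *minima*; a correlation "crosses"
only by strictly exceeding a band. Under the jitter null the observed
correlation is exchangeable with the surrogates, so the probability
that it crosses the upper band anywhere is at most `m/(M+1) <=
alpha/2`, and likewise below — family-wise control at `alpha` exactly,
with no distributional assumptions. The bands are deliberately flat
across bins: per-bin quantile bands cannot control a small family-wise
level when bins are numerous relative to surrogates (even the per-bin
surrogate maximum is crossed by a fresh null draw with probability on
the order of `B/(M+1)` for `B` bins — with 300 bins and 1000
surrogates, several percent at a nominal 1%), which simulation
confirms. The cost of flatness is reduced adaptivity if the null rate
varies strongly across lags; jitter nulls of perievent histograms are
close to flat, so the cost is small here. The measured family-wise
crossing rate under the null design (500 sessions) is 0–0.2% at the
nominal 1%, reflecting the additional conservatism of discrete counts.
`n_surrogates = 1000` at `alpha = 0.01` gives `m = 5`; at least 199
surrogates are required at this level.

## State comparisons

`state_rates()` computes per-bout event rates (events/min, or Hz for
spikes), the Wilcoxon matched-pairs signed-ranks test on successive
wake/sleep bout pairs within a subject (requiring 20 pairs), and
`state_rate_test()` runs the across-subject paired t test on
per-subject state means. `stimulation_state_comparison()` splits
stimulations by the state they fall in, extracts per-subject post-
trigger peak rates per state, and compares them with a paired t test;
subjects lacking stimulations in either state are excluded with a
warning. Both tests hold their nominal 5% type-I level within binomial
Monte-Carlo error in the suite's 200-replicate null simulations.

# Infusion Δ-rate analysis

Recordings are split into pre- and post-infusion epochs (30 min each
by default) with the half-open convention (a boundary event belongs to
post). For each epoch and state, the perievent correlation (3 s
window, 50 ms bins) is baseline-subtracted: the mean rate over the
quiescence bins — bin centers in [-1.5, -1.0) s before the trigger —
is subtracted from every bin, making the quiescence mean exactly zero
by construction. The Δ correlation is post minus pre, per bin; group
averages carry the across-subject SEM per bin (subjects, not triggers,
are the unit of replication).

The *expected latency window* for peak-change extraction is derived
from the pooled raw correlations: the contiguous run of bins exceeding
the jitter upper band (containing the largest exceedance), pooling
both epochs; a manual override is available, and pooling across groups
is configurable (default pools whatever sessions are supplied). The
peak change is the signed value of the largest magnitude inside the
window. Group comparisons: within-group paired t (post vs pre),
between-group independent t on percent differences
`100 * (post - pre) / pre` (undefined and flagged when pre is zero).

Motor controls: movement and twitch frequencies per minute, and the
tonic firing rate. Tonic means ongoing background activity, so spikes
inside a perievent exclusion window (0.1 s before to 0.5 s after every
movement onset and twitch) are removed and the remainder divided by
the unmasked time — otherwise an unmasked evoked response would appear
as a spurious change in "tonic" rate even though the background is
untouched.

# Numerical choices

* **Filtering** is zero-phase (forward–backward, `signal::filtfilt`)
  with 4th-order Butterworth sections, so perievent latencies are not
  distorted; the band is realized as a high-pass/low-pass cascade,
  which remains numerically stable for bands narrow relative to the
  sampling rate (1–40 Hz at 2.5 kHz), where the equivalent
  transfer-function band-pass overflows.
* **Envelopes** use a first-order exponential smoother with time
  constant 0.01 s (the RMS variant smooths the squared signal). A
  published smoothing constant of "0.01 ms" is read as 0.01 s: 0.01 ms
  is below one EMG sample at 1 kHz and matches the RMS constant used
  elsewhere; the value is a documented configuration default, not
  hidden.
* **Spike thresholding** uses the median absolute deviation, since
  spikes inflate a naive SD; a silent baseline with sparse deterministic
  spikes falls back to the plain SD.
* **Degenerate inputs** return defined results: flat envelopes give a
  single-bout segmentation with a warning; constant surrogate ensembles
  give collapsed (upper = lower) bands; identical pre/post epochs give
  identically zero Δ; identical state peaks give a degenerate paired t
  of exactly 0; a flat MUA signal gives an empty spike train.
* **Problem sizes.** The validation suite runs desk-scale versions of
  the study conditions: 600 s sessions at 1 kHz EMG / 2.5 kHz neural
  rate, 500-session null ensembles for band calibration,
  200-replicate null ensembles for test calibration, and 5–10 subject
  infusion groups with full 30-minute epochs generated at the event
  level. The neural rate stands in for hardware-rate acquisition; all
  analysis operates on filtered/envelope signals where 2.5 kHz is
  ample for a 1–40 Hz band.

# Known limitations

* The band construction is validated by its family-wise guarantee, not
  claimed to replicate any specific published implementation of
  jitter-based bands.
* Flat bands trade per-bin adaptivity for exact control (see above).
* The tone dichotomization threshold and its degenerate-case behavior
  are package choices; the underlying criteria do not specify them.
* Manual second-pass artifact removal is replaced by the automated
  duration/state/frequency criteria plus an optional exclusion-interval
  input; residual artifacts on real data remain the user's
  responsibility.
* Spike extraction is threshold-crossing plumbing, not spike sorting;
  analyses are of multi-unit activity unless sorted spike times are
  supplied.
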