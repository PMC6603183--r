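---
title: "Detecting transient 20-40 Hz LFP events and their spike and behavior correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transient 20-40 Hz LFP events and their spike and behavior correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpevents)
```

## The analysis problem

Ventromedial prefrontal cortex (vmPFC) recordings in freely moving mice
contain short bouts — typically a few hundred milliseconds — of band-limited
20-40 Hz oscillation that stand out from the ongoing local field potential
(LFP). These transient events are of interest because their incidence is
reduced in chronically stressed, socially avoidant animals, a subset of
single units is transiently inhibited while they occur, and their rate
co-varies with social-interaction behavior. `lfpevents` implements the
complete analysis chain for such data: event detection from a z-scored RMS
envelope, event statistics (rate, inter-event intervals, duration,
oscillation frequency), event-triggered spike analysis, social-interaction
scoring, and group-level statistics — together with a synthetic
ground-truth generator so that every stage can be validated quantitatively
without access to in-vivo recordings.

## Detection model

Detection operates on one LFP channel at a time (2 kHz sampling is the
reference configuration):

1. **Band-pass filter.** A zero-phase Butterworth band-pass (default order
   3, applied forward and backward with `signal::filtfilt`) at 20-40 Hz.
   Zero-phase filtering is essential here: events are later used as
   alignment points for spike rasters, so the filter must not shift event
   timing. The design places the -3 dB points at the band edges; the
   two-pass application doubles edge attenuation while leaving the band
   interior at unit gain.
2. **RMS envelope.** Root-mean-square amplitude over a sliding 100-ms
   window. The window hops in 10-ms steps by default, so durations can be
   resolved finer than the window itself; setting `step = window`
   reproduces non-overlapping binning. Windows that would cross a record
   edge are dropped rather than padded.
3. **z-scoring.** The RMS series is z-scored against its own mean and SD
   over the entire analyzed period. This makes the threshold dimensionless
   and insensitive to absolute gain and to broadband noise color, which is
   why the synthetic generator's optional 1/f noise mode does not require
   recalibration.
4. **Thresholding.** Maximal runs of envelope samples at or above
   `threshold_z` (default 4 SD) become candidate events; a candidate
   qualifies only if its duration strictly exceeds `min_duration`
   (default 0.2 s). Events are non-overlapping and sorted by onset.
   Candidates separated by brief sub-threshold gaps are *not* merged by
   default; a `merge_gap` option exists for users who want it.

### Event boundaries and the duration criterion

Envelope values are timestamped at window centers. Because a 100-ms window
that merely grazes a strong burst already crosses threshold, the raw span
of suprathreshold window centers overstates the true burst duration by up
to one full window. Reported event boundaries are therefore the first and
last suprathreshold centers pulled *inward* by half the RMS window. For
well-resolved bursts this estimator is unbiased to within about one hop
step; near the detection threshold it errs short rather than long. The
practical consequence, verified in the test suite, is that a 0.15-s burst
is never reported as exceeding the 0.2-s criterion no matter how large its
amplitude, while 0.5-s bursts always are.

A related subtlety is **duration censoring**: the operational definition
of an event includes the >200 ms rule, so any burst whose measured
duration falls at or below 0.2 s simply is not an event. When the
synthetic generator injects bursts with a broad duration spread (the
default is normal with mean 0.3 s, SD 0.1 s), the detected event rate is
accordingly lower than the injected burst rate — not a detector failure
but the criterion doing its job. Rate-recovery checks therefore inject
bursts well clear of the criterion (0.4 s or longer).

### Descriptive statistics

* `event_rate()` is a plain count over analyzed time; at the reference
  conditions, spontaneous vmPFC-like events occur at about 0.05 events/s.
* `inter_event_intervals()` reports onset-to-onset gaps and the fraction
  of intervals strictly below given cutoffs (default 10 s and 20 s). The
  boundary convention is strict `<`: an interval of exactly 10 s does not
  count as "within 10 s".
* `estimate_osc_frequency()` assigns each event the frequency of maximal
  mean Morlet power over its span, searched on a 0.5-Hz grid over
  15-45 Hz — slightly wider than the detection band so that events at the
  band edges are not clipped. Ties break toward the lower frequency. In
  ground-truth tests the estimate lands within a fraction of 1 Hz of the
  injected frequency.
* `threshold_sweep()` recomputes the rate over thresholds 3-6 SD with a
  single envelope computation; the rate is non-increasing in the
  threshold by construction.

## Time-frequency analysis

`morlet_spectrogram()` computes power by frequency-domain convolution with
complex Morlet wavelets: each row is the squared magnitude of the analytic
signal obtained by windowing the trace's FFT with a Gaussian centered on
that frequency. The width parameter is 7 cycles by default — a standard
compromise between time resolution (about 37 ms at 30 Hz) and frequency
resolution (about 4 Hz at 30 Hz). The default grid is logarithmic from 1
to 250 Hz; power is returned at the native sampling resolution (0.5-ms
bins at 2 kHz), optionally z-scored per frequency row across the whole
record. Power scales quadratically with signal amplitude, and memory
scales as frequencies times samples, so spectrograms of long sessions are
best computed on excerpts.

## Spike analysis

`event_triggered_raster()` re-references spike times to event centers
(window ±5 s by default, boundary inclusive), and `compute_peth()` bins
them (100-ms bins by default, matching the envelope resolution) into a
peri-event time histogram that conserves spike counts exactly.

`event_rate_modulation()` quantifies per-cell suppression: for each event
it pairs the firing rate inside the event's own span with the rate in a
baseline window 1-5 s before the event center, then applies a two-tailed
paired t-test across events. Using each event's own `[onset, offset]`
span rather than a fixed window respects the wide spread of event
durations; a fixed-window analysis can be emulated by supplying events
with constant spans. The headline effect size is the percentage of
baseline, `100 * mean(in-event) / mean(baseline)`; an injected
suppression to 50% is recovered within a few percentage points at 200
events and a 5-Hz baseline. Baseline windows are trimmed at the epoch
start and at their own event's onset; events whose baseline overlaps a
*neighboring* event are kept by default (an exclusion flag exists),
since at a typical 0.05 events/s such overlaps are rare and excluding
them discards data without changing the estimate materially. Units with
baseline rates at or below 0.5 Hz are flagged rather than silently
dropped (`included` column in pipeline output); units averaging above
10 Hz are flagged as putative fast-spiking interneurons.

## Behavior

The social-interaction test places the animal in a 39.3 cm x 39.3 cm
arena with a mesh cage against one wall; the interaction zone (IZ) is the
14.5 cm x 26 cm rectangle extending 8 cm around the cage
(`interaction_zone()` preset). Occupancy is counted frame-wise at the
native 15-Hz tracking rate, boundary inclusive, with the animal treated
as a point (centroid). The SI ratio is IZ time with the target present
divided by IZ time without it (two 150-s sessions). Defeated mice with
ratio < 1 are classified stress-susceptible, > 1 stress-resilient;
non-defeated mice with ratio > 1 are controls, otherwise excluded. A
ratio of exactly 1 satisfies neither inequality; rather than forcing a
side, `si_classify()` emits the distinct label `"boundary"`.
Locomotion speed follows the standard recipe: the 15-Hz track is
decimated to 3 Hz (every 5th frame) and speed is displacement per
~333-ms frame.

## Statistics

Group comparisons use a two-tailed Mann-Whitney U test reporting
`min(U_x, U_y)` together with the magnitude of the continuity-corrected,
tie-corrected normal deviate Z — the form under which such results are
conventionally reported. Exact p-values (from the exact Wilcoxon
distribution) are used automatically for tie-free samples up to n = 20
per group; the exact-with-ties path enumerates group labelings when
feasible. The exact mode reproduces brute-force enumeration for all group
sizes up to 7, and both tests hold their nominal type-I error on null
simulations. Paired designs (event-locked modulation, pre/post treatment
event rates) use the classical paired t-test with explicit degrees of
freedom. Multiple pairwise region contrasts are Bonferroni-adjusted; the
correction factor defaults to the number of pairs tested and can be set
explicitly (e.g. `m = 2` for the two planned contrasts against vmPFC).

## The synthetic generator: what it emulates, and what it does not

`generate_lfp()` embeds sinusoidal bursts in Gaussian white noise
(optionally 1/f): Poisson onsets thinned by a refractory gap (default
1 s, which also keeps bursts non-overlapping), frequency uniform over the
configured band, amplitude expressed in units of the background SD
(default 8), and 25-ms raised-cosine on/off ramps to avoid the spectral
splatter of rectangular edges. Ground-truth onsets and offsets refer to
the ramp half-maximum points. Durations are normal (0.3 ± 0.1 s,
truncated at the ramp length), reflecting events that last hundreds of
milliseconds and rarely exceed half a second. `generate_spiketrain()` is
an inhomogeneous Poisson process generated exactly by thinning, with the
rate multiplied by a suppression factor inside events.
`generate_trajectory()` schedules the exact number of in-zone frames
(split into a few contiguous visits) and fills in a reflected random
walk; its only contract is occupancy to within one frame — kinematic
realism is deliberately out of scope. `generate_cohort()` assembles a
full study on disk (per-mouse LFP binaries, spike tables, session
tracks, manifest, ground truth) with configurable group-level event-rate
differences.

What passing tests on these synthetics do *not* show: robustness to
movement and lick artifacts, volume conduction, electrode drift,
non-sinusoidal or frequency-modulated burst morphology, or spike-sorting
errors — none of which the generator models. The background spectrum of
real cortical LFP is colored and nonstationary; the z-scored envelope
makes detection insensitive to stationary coloring, but slow
nonstationarities in real data may call for per-segment normalization.

## Numerical and design choices

* Thresholding uses a single threshold with no hysteresis; boundaries are
  the (half-window-corrected) first/last suprathreshold envelope samples.
* `>200 ms` is read as strictly greater; `>0.5 Hz` baseline inclusion and
  `>10 Hz` interneuron flagging are likewise strict.
* The envelope z-score degenerates when the RMS series is (numerically)
  constant — a constant signal, or a pure tone whose period divides the
  window exactly; this raises a degenerate-input error rather than
  returning amplified rounding noise.
* Electrode depth maps to region by the 2-mm rule (deeper than 2 mm from
  the cortical surface is vmPFC, shallower is dmPFC); ACC labels are
  always explicit.
* Reproducibility: every generator takes an explicit seed and restores
  the caller's RNG state; cohort generation and the pipeline are
  bit-reproducible functions of (config, seed), which the test suite
  verifies by hashing the written files.
* Problem sizes in the validation suite were chosen to give the
  statistical properties clear margins at desk scale: 100-seed
  Monte-Carlo runs on 1000-s records for detector sensitivity and
  precision, 200 events per unit for modulation recovery, and cohorts of
  10 electrodes per group for the group-level comparisons.

## A worked example

```{r example, eval = FALSE}
sim <- generate_lfp(600, fs = 2000,
                    spec = event_spec(rate = 0.05, amplitude = 10,
                                      duration_mean = 0.4,
                                      duration_sd = 0.05),
                    seed = 1)
ev <- detect_events(sim$record)
summary(ev)
inter_event_intervals(ev)$fraction_within
```

The full pipeline over a synthetic cohort:

```{r pipeline, eval = FALSE}
dir <- tempfile()
generate_cohort(cohort_config(), dir, seed = 1)
out <- run_pipeline(list(dataset = dir))
read_results_table(file.path(out, "group_tests.csv"))
```

## Known limitations

* Detected durations carry a downward bias of up to roughly half an RMS
  window for events near the detection threshold; duration-sensitive
  analyses should treat values within one window of the criterion with
  care.
* The oscillation-frequency estimate assigns a single peak frequency per
  event; genuinely multi-peaked events resolve to the lower peak.
* The Mann-Whitney exact-with-ties mode enumerates labelings and is
  limited to moderate sample sizes; beyond that the tie-corrected normal
  approximation is used (with a warning when it replaces a requested
  exact computation).
* The pipeline assumes the manifest layout written by
  `generate_cohort()`; adapting real recordings means writing a manifest
  plus the binary/CSV formats of `write_lfp()`, `write_spike_table()`
  and `write_track()`.
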