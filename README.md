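# lfpevents

Detection and analysis of transient 20–40 Hz oscillatory events in local
field potential (LFP) recordings, with the downstream analyses that give
those events meaning: event-locked single-unit modulation,
social-interaction behavior scoring, and group-level statistics.

The package is aimed at systems-neuroscience analysts working with
extracellular recordings from the rodent medial prefrontal cortex (or any
region producing short band-limited oscillatory bouts), and at anyone who
needs a fully testable reference implementation of this analysis style:
every stage can be validated against a built-in synthetic ground-truth
generator, so the whole chain runs and is checked without any in-vivo
data.

## Method

An event is a transient bout of band-limited oscillation that stands out
from the ongoing LFP. Detection works on the z-scored RMS envelope of the
band-passed trace:

1. Band-pass filter the LFP at 20–40 Hz (zero-phase Butterworth, so event
   timing is preserved for later spike alignment).
2. Compute the RMS amplitude over a sliding 100-ms window (10-ms step).
3. z-score the RMS series against its mean and SD over the whole analyzed
   period: `z_t = (RMS_t − μ) / σ`.
4. Maximal runs with `z_t ≥ θ` (default threshold θ = 4 SD; the standard
   calibration range 3–6 SD is available via `threshold_sweep()`) become
   events if their duration strictly exceeds 200 ms.

Each event gets a center, peak z, and an oscillation frequency (peak of
mean Morlet wavelet power over the event span, searched over 15–45 Hz).
Spike modulation is quantified per cell by pairing, for each event, the
firing rate inside the event span with the rate 1–5 s before the event
center, and testing across events with a paired *t*-test; the effect size
is the percentage of baseline, `100 · mean(rate_in) / mean(rate_baseline)`.
Social-interaction behavior is scored as the SI ratio — interaction-zone
occupancy with a target mouse present divided by occupancy without it —
with defeated animals classified susceptible (ratio < 1) or resilient
(ratio > 1). Group contrasts use two-tailed Mann–Whitney U tests
(reporting U and the tie-corrected normal deviate Z, exact p-values for
small tie-free samples) with Bonferroni adjustment over planned pairs.

## Worked example

Simulate a 600-s channel with bursts injected at 0.05 events/s, 10× the
noise SD, then detect:

```r
library(lfpevents)

sim <- generate_lfp(600, fs = 2000,
                    spec = event_spec(rate = 0.05, amplitude = 10,
                                      duration_mean = 0.4,
                                      duration_sd = 0.05),
                    seed = 1)
nrow(sim$ground_truth)   # 23 bursts injected (Poisson draw at rate 0.05/s)

ev <- detect_events(sim$record)
summary(ev)
#> 23 events in 600.0 s (rate 0.03833 events/s)
#> duration (s):
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.2200  0.2900  0.3100  0.3222  0.3650  0.4400
#> peak z:
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   4.905   7.393   9.083   8.254   9.306   9.611
#> oscillation frequency (Hz):
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   20.00   23.25   29.00   28.89   34.25   39.50
```

All 23 injected bursts are recovered, none spuriously: the detected rate
equals the realized injected rate for this draw (23/600 s; the Poisson
expectation is 30). Durations cluster around 0.3 s, peak z values sit
well above the 4-SD threshold, and estimated oscillation frequencies span
the injected 20–40 Hz band.

The canonical small-sample statistics behave as textbook oracles say they
must:

```r
mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#>   Mann-Whitney U test (two-tailed, exact)
#>   U = 0, n_x = 3, n_y = 3, p-value = 0.1
paired_t(c(1, 2, 3), c(0, 0, 0))$statistic   # t = 2 * sqrt(3) = 3.464, df = 2
si_classify("SD", time_no_target = 60, time_target = 30)
#>   <si_result> SD mouse: IZ 60.0 s / 30.0 s, SI ratio 0.5 -> susceptible
```

A complete synthetic study (LFP binaries, spike tables, tracking,
manifest) and the full pipeline over it:

```r
dir <- tempfile()
generate_cohort(cohort_config(), dir, seed = 1)
out <- run_pipeline(list(dataset = dir))
list.files(out)
#> electrode_rates.csv events.csv group_tests.csv modulation.csv
#> peth.csv run_manifest.json si_summary.csv threshold_sweep.csv
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/lfpevents.R` (subcommands `simulate`, `detect`, `sweep`,
`spectrogram`, `peth`, `modulation`, `si`, `compare`, `run`).

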