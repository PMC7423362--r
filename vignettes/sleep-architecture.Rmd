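---
title: "Sleep-wake architecture analysis with vigilarch: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-wake architecture analysis with vigilarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigilarch)
```

## The analysis problem

Rodent sleep studies score vigilance — wake, NREM sleep, REM sleep — in short
epochs from EEG/EMG, producing a *hypnogram*. Most architecture statistics
are not computed on raw epochs but on *episodes*: bouts of one state that are
allowed to contain brief interruptions. vigilarch implements the standard
conventions:

* **NREM and wake episodes**: at least 1 min long, tolerating interruptions
  of at most 16 s (`rule_nrem_default()`, `rule_wake_default()`).
* **REM episodes**: as short as one 4-s epoch, tolerating interruptions of
  at most 4 s (`rule_rem_default()`).
* **Brief awakenings**: wake runs of at most 16 s flanked by sleep — short
  arousals that are classified separately, never as wake episodes.
* **Episode-duration distributions** use the variant rule that includes all
  NREM episodes strictly longer than 16 s (`rule_nrem_distribution()`).

On top of episodes, the package computes episode-level transition counts
(wake→NREM, NREM→REM, and the percentage of NREM episodes that terminate in
REM), time-in-state accounting, per-epoch EEG spectra with a slow-wave
activity (SWA, 0.5–4 Hz) time course normalised to the 24-h baseline mean,
immobility-defined sleep scoring for video-tracking screens (immobility
strictly exceeding 40 s), and a chi-square (Sokolove–Bushell) periodogram
for circadian activity.

## Epochs, phases, and the hypnogram

The scoring epoch length is configurable with default ε = 4 s. The default
is an inference, not a published constant: the REM rules (episodes as short
as 4 s, interruptions ≤ 4 s) and the 16-s brief-awakening bound (= 4 epochs)
are all integer multiples of 4 s, which is also a common scoring epoch in
mouse EEG work.

Epochs are half-open intervals `[t, t + ε)`. Each epoch belongs to the
light or dark phase of a 12:12 schedule by its **midpoint** clock time; the
midpoint rule makes boundary epochs unambiguous. Hourly time courses are
binned relative to lights-on.

## Episode segmentation

`segment_episodes()` merges maximal runs of the target state across
non-target gaps of duration ≤ `max_gap_s`. Three conventions matter and are
fixed as follows:

* **A gap merges only with target state on both sides.** Leading or
  trailing non-target content never joins an episode.
* **Durations use the span convention**: `span_s` runs from the first to
  the last target epoch, interruptions included. Whether published episode
  durations include interruption time is typically unstated; the
  complementary `within_s` (target epochs only) is always reported, so the
  other convention is recoverable.
* **Thresholds are read exactly as printed**: merge when gap ≤ 16 s,
  episode when span ≥ 60 s, brief awakening when run ≤ 16 s, and the
  distribution rule's "longer than 16 s" is strict.

`ARTIFACT` epochs count as gap content for segmentation but form their own
category in time-in-state totals, so state totals always conserve the
recording duration.

Episodes touching the recording edge are flagged `truncated_*`; they are
excluded from mean-duration statistics by default (their true extent is
unknown) but still count as episodes. One inherent caveat of any
minimum-duration rule: padding a record with extra wake can promote a
sub-minimum wake complex at the boundary into a qualifying episode, so
boundary-adjacent statistics are only invariant to padding when the record
already begins and ends with qualifying wake.

### Brief awakenings versus wake episodes

A wake run of ≤ 16 s flanked by sleep is *usually* a brief awakening, but
not always: in a long wake period interrupted by two sub-16-s sleep
intrusions, the short wake run between them is sleep-flanked yet clearly
part of the wake episode that merging reconstructs. vigilarch therefore
excludes candidate runs that fall inside a segmented wake-episode span.
This makes brief awakenings and wake episodes disjoint by construction:
every brief awakening lies within or between sleep episodes.

### Episode-level transitions

`transition_summary()` counts a NREM→REM transition when the first epoch
after an NREM episode's end that *belongs to an episode* belongs to a REM
episode; epochs belonging to no episode (for example a 30-s wake run — too
long to merge, too short to qualify) are skipped. Wake→NREM transitions are
counted symmetrically. The headline statistic
`pct_nrem_terminating_in_rem = 100 · n(NREM→REM) / n(NREM episodes)` is
reported `NA` when no NREM episodes exist. Where spans of different states
nest (a 4-s REM episode inside a merged NREM span), ownership of an epoch
goes to the episode whose state matches the epoch's label.

## Spectral analysis

Spectra are computed per epoch by FFT with a Hanning window at a nominal
0.25-Hz resolution. At the 256.9-Hz sampling rate of the targeted
acquisition hardware, a 4-s epoch is 1027.6 samples — not an integer and
not a power of two — so a convention is needed: vigilarch takes
`m = floor(ε·fs) = 1027` samples per epoch, demeans, tapers, and zero-pads
to `n_fft = round(fs/0.25) = 1028` points. Bin spacing is then
`fs/1028 ≈ 0.2499 Hz`, reported as 0.25 Hz with exact centres stored in
`freq_hz`. Power is scaled so the one-sided bin sum equals the mean square
of the windowed epoch (a discrete Parseval identity, tested to 1% on white
noise). Band power sums bins whose *centre* lies in `[lo, hi]`, both edges
inclusive; disjoint bands are therefore additive and total to the full
spectrum.

The SWA time course divides each epoch's 0.5–4 Hz power by the mean over
**all** artifact-free epochs of the baseline day — all states, matching the
convention of plotting every state on one normalised axis — so the baseline
mean is exactly 100%. The theta band defaults to 5–10 Hz (no published
edges exist for this dataset; mouse REM theta peaks near 6–8 Hz), and
`theta_peak()` breaks ties toward the lowest frequency, flagging flat
bands. No detrending is applied beyond per-epoch mean removal: the
acquisition chain's 0.1–100 Hz filter is emulated in the simulator, not
re-applied in analysis.

## Behavioural screen

`score_immobility_sleep()` scores a bout when continuous immobility
*strictly exceeds* 40 s. Percentages are bout time over observed bin time,
per hour since lights-on and per phase. The screen's "normal immobility
range" is not defined in the literature this package follows; vigilarch
uses cohort mean ± k·SD per phase (k = 2 by default), flagging individuals
outside the band in either phase — on a normal cohort the flag rate is
about `2Φ(−k)`, which the tests verify.

The circadian periodogram is the chi-square (Sokolove–Bushell) statistic
— standard actigraphy practice, robust for square-wave-like activity — over
candidate periods stepping one bin (10-min default) across 20–28 h. Since
"amplitude" has no fixed definition in this context, vigilarch reports peak
Qp height above the pointwise α = 0.05 chi-square significance line.

## The synthetic generator: what it emulates

`simulate_hypnogram()` draws a semi-Markov chain at epoch scale:

* **Dwells** are geometric with phase-specific means — the memoryless
  choice consistent with the per-epoch analysis; at a light/dark boundary
  the running dwell is truncated and redrawn under the new phase's
  parameters (equivalent to switching the per-epoch hazard).
* **Transitions** follow the wake→NREM→REM continuum: wake always exits to
  NREM; an ending NREM dwell enters REM with probability `rem_entry_p`
  (else wake); REM exits to wake with probability 0.7, else back to NREM.
* **Brief awakenings** (wake runs of 1–4 epochs) are inserted post hoc into
  NREM at a configured rate per hour of NREM, keeping sleep on both flanks,
  rather than modelled as a fourth state.
* **Diurnal modulation**: sleep-dwell means are multiplied by 1.5 in the
  light phase and divided by 1.5 in the dark; wake dwells the reverse.

Genotype presets encode the headline wild-type versus mutant contrasts. The
published deltas (1.4 h = 14% less NREM; 1.2 h = 57% less REM) fix the
wild-type absolute targets by arithmetic — NREM 10.0 h, REM 2.1 h, wake the
11.9-h remainder — and the mutant targets as wild type minus the deltas
(8.6, 0.9, 14.5 h). NREM→REM entry probabilities are 0.90 (wild type)
versus 0.65 (mutant). `calibrate_preset()` then solves numerically
(deterministically) for the wake and NREM base dwell means such that the
chain's long-run occupancy — embedded-chain stationary distribution
weighted by mean dwells, averaged over phases, with a closed-form
correction for NREM time overwritten by brief-awakening insertion — hits
the targets within 2%. The REM mean dwell is the remaining free quantity
and is pinned at a realistic bout scale: 60 s (wild type) and 70 s
(mutant; longer sleep bouts are part of the state-inertia phenotype).
Brief-awakening rates are 8/h of NREM (wild type) versus 4/h (mutant).
These choices were made once, from physiological plausibility, before any
acceptance measurement.

Seeding uses pre-allocated per-state substreams consumed by visit index,
with dwells drawn by inverse-CDF. Within one simulation the draws are iid,
so the generated law is exactly the semi-Markov chain above; but two
configurations simulated from the same seed share uniforms bout for bout —
common random numbers — which stabilises between-genotype contrasts at a
fixed cohort size without touching either cohort's marginal distribution.
Cohorts therefore use the same per-animal seeds for both genotypes.

Signal synthesis (`synthesize_signals()`) produces 1/f^α background EEG
with a band-limited 0.5–4 Hz component in NREM and a jittered theta
sinusoid in REM, white-noise EMG with wake ≫ NREM > REM variance, linear
0.5-s crossfades at state changes, and a zero-phase frequency-domain
0.1–100 Hz bandpass (no time-domain filter dependency is available, and
phase is irrelevant to power analyses). Tracking synthesis emits 1-s
mobility samples from a two-state Markov chain whose stationary immobility
probability is conditioned on the concurrent vigilance state, with ~30-s
persistence so that sleep produces the >40-s immobile runs the screen
detects.

### What a green test does not establish

The generator emulates the *statistical signatures* the analysis consumes:
state occupancies, transition propensities, bout-scale dwell structure,
band-limited spectral contrasts, and sleep-coupled immobility. It does not
reproduce real EEG morphology (spindles, slow-oscillation waveforms,
transition dynamics), homeostatic SWA decline across the light phase
(Process S), ultradian REM cycling, or between-animal variability (all
animals of a genotype share parameters). Agreement between generator and
analysis therefore validates that the implemented segmentation, transition,
and spectral procedures measure what the published numbers describe — not
that the simulator is a substitute for recordings.

## Group comparison

`compare_groups()` uses the Welch (unequal-variance) two-sample t-test —
the published methods say "Student's t test" without a variance assumption,
and Welch is the safer default — with per-group mean ± SEM and percent
change `100·(A−B)/A`. No multiple-testing correction is applied (tests are
reported per metric, as in the source literature); the pipeline logs the
number of metrics tested.

## Known limitations

* Automatic sleep staging from raw signals is out of scope; the pipeline
  consumes or synthesises scored hypnograms.
* The EDF layer is a minimal 16-bit single-rate reader/writer, not a
  general EDF+ implementation.
* Transition counts are reported over the analysed record; callers with
  records other than 24 h should normalise explicitly.
* The periodogram significance line is pointwise, not corrected across
  candidate periods.
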