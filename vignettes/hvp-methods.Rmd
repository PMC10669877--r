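---
title: "High variability periods in EEG: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High variability periods in EEG: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvpeeg)
```

## The measure

EEG amplitude does not fluctuate at a constant intensity: a single channel
alternates between stretches where the signal swings widely and stretches
where it is comparatively quiet. `hvpeeg` quantifies that alternation
directly, without any spectral transform, by three steps:

1. **Moving-window amplitude SD.** For a window of `m` seconds slid along a
   channel (advancing `m * (1 - overlap)` seconds per step), compute the
   standard deviation of the amplitude about the window mean, with the
   *population* denominator (the number of samples in the window), in
   microvolts. This is the A\_SD trace (`compute_asd()`).
2. **Rank-percentile threshold.** The threshold `T` is the `i`-th value of
   the ascending rank-ordered A\_SD values, with `i = ceiling(p * n / 100)`
   clamped to `[1, n]` and `n` the number of emitted windows
   (`compute_threshold()`). The default `p = 25` is the quartile cutoff.
3. **Segmentation and summaries.** Maximal runs of windows with A\_SD
   strictly above `T` are high variability periods (HVPs); runs at or below
   `T` are low variability periods (LVPs) (`segment_trace()`). The
   summaries (`hvp_summary()`) are the mean HVP duration (HVP-D, s), mean
   HVP area (HVP-A, summed A\_SD over the run times the window step,
   microvolt-seconds), mean LVP duration (LVP-D, s), the HVP rate (HVP-R,
   events per minute) and the HVP-D/LVP-D ratio.

When two conditions are compared (rest against task, rest against
anesthesia), the threshold must be a single absolute microvolt value:
`anchored_pipeline()` computes `T` per channel on a baseline condition
(conventionally eyes-closed rest) and applies it unchanged everywhere else.
Otherwise each condition would be segmented against its own amplitude scale
and the comparison would be circular.

## Parameter choices

* `window_seconds` (default **10 s**): windowed SD estimates stabilise at
  around 10 s for resting EEG; much longer windows converge to the global SD
  and stop resolving the alternation. For short 5-minute anesthesia blocks a
  3 s window is used so that enough windows exist for the rank threshold.
* `overlap` (default **0.5**): the conventional default for window-based
  EEG analysis; outcomes are only mildly sensitive to it.
* `percentile` (default **25**): low enough to keep most genuine
  variability above threshold, high enough to exclude the noise floor. Note
  a structural consequence of the rank definition used throughout: at
  percentile `p`, the fraction of windows above threshold is forced to
  `1 - p/100` (exactly, up to ties), whatever the signal.

Two deliberate interpretation choices are exposed as options:

* **Durations are crossing times.** A run of `k` windows has duration
  `k * step_seconds`. A textbook variant that multiplies run lengths by the
  full window length `m` — which over-counts when windows overlap — is
  available as `hvp_summary(duration = "literal")` for audit.
* **Ties go to LVP.** The HVP definition is strictly supra-threshold, so a
  value exactly equal to `T` is low-variability. A constant trace therefore
  has no HVPs.
* **Boundary runs.** The first and last segments abut the recording edges
  and are flagged `truncated`; they are included in the means by default and
  can be excluded with `include_truncated = FALSE`.

## The synthetic generator

`synth_recording()` builds EEG-like test signals: 1/f-coloured background
noise plus narrow-band oscillations (e.g. a 10 Hz alpha component),
multiplied by a two-state amplitude envelope that alternates between high-
and low-SD epochs with gamma-distributed durations (shape 4, so degenerate
very short epochs are rare; exponential optional) and 0.5 s raised-cosine
ramps at the transitions to avoid spectral splatter. The epoch boundaries
are returned as ground truth, which makes parameter-recovery testing
possible without any recorded data.

**Duty cycle default.** The default mean low-epoch duration is one third of
the mean high-epoch duration. This follows from the rank-threshold
arithmetic above: at the default `p = 25`, exactly 25% of windows fall below
threshold, so an envelope that spends 25% of its time in the low state
places the threshold on the transition ramps — threshold crossings then
coincide with programmed epoch boundaries and recovered HVP-D tracks the
programmed high-epoch mean. With any other duty cycle the rank threshold
lands inside one of the two state distributions and segment boundaries
detach from envelope boundaries; that is a property of the measure, not of
the generator.

**Resolution limit.** Epochs shorter than about twice the analysis window
cannot be resolved: a 10 s window straddles a 5 s low epoch completely, no
window is ever fully quiet, and adjacent high epochs merge. The generator
warns when the programmed means are in this regime. In recovery experiments
with 10 s windows, programmed high-epoch means of 30 s and 60 s are
recovered to within roughly 13% and 3% respectively, while a 15 s mean
(whose companion low epochs average 5 s) is systematically over-estimated —
the recovered durations are window-limited, as the warning says.

What the generator does *not* emulate: eye blinks and muscle artifact,
slow drifts of arousal across a recording (the envelope is a stationary
alternating-renewal process), biophysically realistic source mixing, or
channel-to-channel correlation (channels are drawn independently). Passing
recovery tests on these signals therefore demonstrates the correctness of
the segmentation arithmetic, not robustness to artifacts.

Two profile helpers encode the study conditions used throughout the tests:
`synth_condition_pair()` (an eyes-closed-like baseline with stronger alpha
and shorter high epochs against an eyes-open-like condition with high epochs
twice as long) and `synth_anesthesia_session()` (rest / low / deep /
recovery blocks in which variance structure is progressively damped; under
a rest-anchored threshold HVPs vanish in the deep block and do not reappear
in early recovery).

## Comparator metrics

* **Sample entropy** (`sample_entropy()`): embedding 2, tolerance 0.2 times
  the signal SD, Chebyshev distance, self-matches excluded — the common
  community parameterisation, exposed as arguments. If no template pair
  matches, `Inf` is returned rather than an error.
* **Lempel–Ziv complexity** (`lempel_ziv()`): median binarisation followed
  by LZ76 exhaustive-history phrase counting, normalised by `n / log2(n)`.
  A trailing phrase still reproducible from history is not counted, so a
  constant signal has phrase count 1.
* **Waveform complexity** (`waveform_complexity()`): a documented variant —
  non-overlapping z-scored segments greedily clustered by correlation at or
  above 0.8 against each cluster's founding segment; complexity is the
  cluster count over the segment count.
* **Harmonic-regression duration** (`hr_duration()`): per moving window a
  nonlinear least-squares fit of `a * sin(b t + c)` (Levenberg–Marquardt,
  at most 200 iterations, tolerance 1e-8), with `b` initialised at the
  window's dominant FFT frequency, `a` at RMS·√2 and `c` at 0;
  non-convergent windows keep their initial `a` and are flagged. The
  per-window |a| sequence is thresholded at its own quartile and segmented
  with the same run machinery as A\_SD; the mean supra-threshold run
  duration is returned. Amplitudes are reported at the fit tolerance
  (8 significant digits) so sub-tolerance jitter cannot fabricate
  threshold crossings — a constant-amplitude sinusoid yields duration 0.
* **Relative band powers** (`band_powers()`): Welch spectra (Hann, 4 s
  segments, 50% overlap), conventional edges delta 0.5–4, theta 4–8, alpha
  8–12, beta 12–30, gamma 30–45 Hz, normalised by total 0.5–45 Hz power;
  the band edges are configurable since only the effective bandwidth of the
  recording hardware constrains them.

Two structural facts about these comparators showed up consistently in the
package's own simulations and are worth knowing before interpreting
correlation tables:

* On envelope-driven synthetic cohorts, HVP-D is essentially uncorrelated
  with sample entropy, Lempel–Ziv and waveform complexity (|r| well below
  0.4), but **harmonic-regression duration is strongly correlated with
  HVP-D by construction** — it is the same supra-quartile run-duration
  statistic applied to the fitted amplitude envelope, and when the envelope
  is the only thing that varies, the two move together. Low HVP-D/HR-D
  correlations reported on real recordings must therefore be driven by
  signal features the generator does not model.
* For a stationary two-state envelope, mean LVP duration *rises* with the
  threshold percentile (more windows fall below a higher threshold, and
  sub-threshold runs lengthen); mean HVP duration falls. Reports of both
  durations falling as the percentile rises require slow nonstationarity
  that concentrates the deepest windows in a few long stretches, which the
  generator deliberately omits.

## Classification protocol

`build_features()` assembles one row per subject and condition from
channel-averaged metrics (averaging restricted to a named electrode subset:
`ALL`, `F8`, `F4_1`, `F4_2`, `T4`). The default `"hvp"` feature set is the
three numbered HVP summaries (HVP-D, HVP-A, LVP-D); `"other"` is sample
entropy plus HR duration; `"spectral"` is the five relative band powers
plus the theta/beta ratio; `"all"` is all eleven.

`train_eval()` repeats a 75/25 split ten times, fits a boosted decision-tree
ensemble (logistic objective, maximum depth 3, 50 rounds, learning rate 0.3,
exact greedy splits — appropriate for tables of a few dozen rows) and
averages held-out accuracy, sensitivity, specificity, recall, precision and
F1. **Splits are by subject**, keeping both of a subject's rows in one
partition: a row-level split would let the model see the test subject's
other condition during training and inflate scores; the leaky variant
remains available as `split_unit = "row"` for audit. The positive class is
the second condition label alphabetically.

## Group statistics

`paired_compare()` is a two-sided paired t-test per metric and condition
pair across subjects; `tukey_hsd()` is a one-way ANOVA with Tukey's honest
significant difference over condition groups. Both report differences as
condition2 − condition1 with conditions sorted alphabetically, and
`compare_conditions()` emits both, labelled, since published difference
tables do not always say which adjustment produced their p-values. Group
summaries (`aggregate_metrics()`) average across channels within subject
first, then take mean and standard error across subjects.

## Numerical notes

* A\_SD is computed from cumulative sums after removing the global channel
  mean, which keeps the one-pass variance formula stable under large DC
  offsets; outputs are offset-invariant to ~1e-9 and scale-equivariant to
  machine precision.
* Windows are `round(m * rate)` samples; trailing samples that do not fill
  a window are dropped; non-finite samples abort with the offending index.
* The EDF dialect quantises to 16 bits over each channel's physical range;
  the CSV dialect writes 17 significant digits and round-trips doubles
  bit-exactly. Unknown physical units in EDF headers are an error, never a
  silent rescale.
* Resampling uses FIR anti-aliased decimation in stages (integer factors)
  or polyphase rational resampling otherwise.
* All segment times are seconds from recording start, half-open intervals
  `[start, end)`.

## Problem sizes used in the shipped checks

The package's tests and the acceptance script run entirely on synthetic
data: recovery cohorts of five recordings per programmed epoch mean (12
cycles per recording), a twelve-subject two-condition cohort at 240 s per
recording, a sixteen-recording orthogonality cohort at 120 s, 5-minute
anesthesia blocks, and ten-repeat classifier runs on 28-row tables. These
sizes put every quantity within a few percent of its asymptote while
keeping a full run in the low minutes on one CPU.
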