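---
title: "Methods: call-linked RA activity and antiphonal calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: call-linked RA activity and antiphonal calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antiphony)
```

## The problem

Female zebra finches exchange short, soft contact calls — *stack* calls
(harmonic, little frequency modulation, up to ~100 ms) and the shorter *tet*
calls — with their partners. Extracellular recordings from the premotor
nucleus RA (nucleus robustus archistriatalis) during free calling show
multiunit activity that is locked to the bird's own call onsets: a dip in
firing shortly before onset, a burst during the call, and a call-type
dependent return to baseline. The same recordings can be interrogated for
*antiphonal calling*: whether the partner's calls cluster within half a
second of the focal bird's calls.

`antiphony` implements that analysis chain as reusable, tested functions,
and pairs it with a synthetic-session generator whose ground truth makes
every stage verifiable: the call exchange, the call-locked firing, the
continuous trace, and the statistics on top of them.

## Call-aligned activity

The central object is the peri-event time histogram (PSTH): spike times are
binned relative to every call onset (time 0) and summed over calls. The
default geometry is **400 bins of 10 ms spanning -2 s to +2 s**, with bins
half-open `[t, t + 10 ms)`, so bin index 200 (0-based) is the first
post-onset bin. Each histogram is z-scored **over its own 400 bins** (sample
SD; a flat histogram maps to z = 0 everywhere) — no separate baseline
period is used, so a long elevation raises the normalizing SD and
compresses its own z-score. That property matters below.

Derived statistics:

* **Call association**: a unit counts as call-associated when any bin
  within ±0.5 s of onset has |z| > 1.73. The threshold is applied
  two-sidedly by default because pre-onset inhibition is as much "a change
  in spiking activity" as the burst; `two_sided = FALSE` restricts it to
  increases.
* **Density windows**: the PSTH is normalized to a probability density over
  bins and averaged (×100) over an *early* window, 0-based bins 199–203
  (-10 ms to +40 ms), and a *late* window, bins 225–250 (+250 to +500 ms).
  A second, wider pair of summary windows (onset to +125 ms; +150 to
  +750 ms) is provided for per-bird z-score summaries. The bin-index
  definition of the late window is taken as authoritative: at 10 ms bins,
  indices 225–250 correspond to +250 to +500 ms, not +25 to +50 ms, and the
  early/late windows must be disjoint.
* **Return to baseline** (`elevated_duration`): scanning forward from
  onset, the time of the first bin where z drops below 2 and stays below it
  for at least 3 consecutive bins; 0 if the unit is not elevated at onset,
  and the window end (flagged `censored`) if it never comes down.

## Communication between two birds

Partner call onsets are histogrammed relative to focal call onsets over
±4 s in 0.1 s bins (a PSTH of one point process against the other) and
z-scored over the 80 bins. `detect_antiphonal` declares communication when
the maximum z within ±0.5 s of zero lag exceeds 2 — one-sided, because only
a *rise* in partner calling counts.

A fixed per-bin threshold over ten tested bins has a substantial familywise
false-alarm level; on sparse counts (short sessions, low call rates) the
rule fires on a sizeable fraction of fully uncoupled sessions, and the
acceptance suite verifies that this rate matches the rate implied by the
z > 2 criterion under an independent Poisson bin-count null rather than
pretending it is 5%. For a calibrated decision,
`detect_antiphonal_surrogate` compares the observed peri-zero peak count
against seeded circular shifts of the partner train and returns a
permutation-style p-value; the demo pipeline reports both.

Each focal call is also labelled with its interaction context: `answer` if
a partner onset falls in the half second *before* it, `answered` if one
falls in the half second *after* it, `none` otherwise. When both sides are
occupied, `answer` wins (a fixed, documented tie-break that keeps the three
labels an exact partition); a partner onset exactly simultaneous with the
focal onset is ignored; the matched partner call is the nearest qualifying
onset.

## Spike pipeline

Detection thresholds the trace at 4.5 robust noise SDs, the noise SD being
`MAD/0.6745` so the spikes themselves do not inflate it. Each
above-threshold excursion contributes its extremal sample as one event;
events closer than the 0.5 ms dead time are merged (earliest wins); a
64-sample snippet is cut with the peak at sample 21 (20 samples before, 44
after, capturing the afterwave). Polarity defaults to `negative`, the
dominant polarity of extracellular somatic spikes. Peaks without room for a
full snippet are skipped.

Sorting is plain k-means on the 64-dimensional snippets, best of 10 random
starts, with `k` chosen by the user (an elbow report over k = 1..8 is
available; no automatic selection). Units are classified by the coefficient
of variation of their interspike intervals: CV < 0.35 with at least 100
spikes is `regular` (the clock-like firing of RA projection neurons),
CV ≥ 0.35 `irregular`, anything smaller-sample `undetermined`. Both cutoffs
are configurable; 0.35 sits between the CV ≈ 0.2 of the simulated tonic
units and CV ≈ 1 of Poisson-like multiunit firing with a wide margin on
both sides.

## The synthetic session

The generator is a first-class module, not a test fixture. It emulates:

* **Call exchange**: the focal bird calls as a homogeneous Poisson process
  with dead time equal to the call duration (stack 90 ms, tet 50 ms, 60%
  stacks by default; 0.1 calls/s over a 20-min default session — the scale
  of one bird's calling in a multi-hour recording). The partner emits an
  independent baseline train (0.05 calls/s) *plus* answers: each focal call
  is answered with probability `p_answer` at a latency drawn from a
  distribution whose support must lie in (0, 0.5] s (default uniform on
  [0.05, 0.45] s). Overlapping partner calls are merged, keeping the
  earliest onset. Answers are added to, not substituted for, the baseline —
  the simplest structure that satisfies the ±0.5 s criterion.
* **Call-locked firing**: an inhomogeneous Poisson train whose rate is the
  40 spikes/s multiunit baseline times the product of piecewise-constant
  kernels around each call onset. The stack kernel dips to 0.3× from -80 to
  -10 ms, bursts to 5× during the 90 ms call, shoulders at 2× and returns
  to baseline by +150 ms. The tet kernel shares the dip and burst but
  decays gradually (3.5, 3, 1.9, 1.4×) and only reaches baseline at
  +750 ms. The tet tail is a graded decay rather than a low flat shelf
  deliberately: with whole-window z-normalization a shelf below about twice
  baseline sits at a structural z ≈ 0.9 *no matter how many calls are
  averaged*, so a flat mild tail can never register on the z = 2
  return-to-baseline criterion; a decaying return crosses it at a
  well-defined time. Since the rate function is piecewise constant, it is
  simulated exactly segment by segment (no thinning), the combined gain is
  capped at 20× baseline with a warning (rate-explosion guard for stacked
  call windows), and a 0.5 ms refractory dead time is enforced.
* **Regular units**: gamma-renewal trains (shape `1/CV²`, mean ISI
  `1/rate`), uncoupled from any call — the rare tonic RA units.
* **Continuous traces**: Gaussian noise (SD 200 on the signed 16-bit
  scale) plus a 64-sample waveform template per unit added at the sample
  nearest each spike time, written as 16-bit PCM mono WAV at 22,050 Hz.
  The two default templates share a sharp trough (SD ~0.09 ms, amplitude
  2000, i.e. SNR 10 against the default noise) and differ in their
  afterwaves, which is what the sorting separates. Templates are kept
  sharp because peak localization in noise degrades quadratically with
  trough width.

Everything is deterministic given the scenario seed; every stage draws from
a named substream of the root seed.

What the generator does **not** emulate: call acoustics (only onsets,
offsets and types exist), electrode drift and nonstationary noise,
superimposed spikes as a waveform phenomenon (overlapping templates simply
add), bursting structure within the multiunit, and any dependence of
calling on the partner beyond the one-way answer coupling. Passing tests
therefore demonstrate that the *analysis* is correct and calibrated on data
with the assumed statistical structure — not that real recordings satisfy
those assumptions.

The detection/sorting benchmark additionally enforces a 4 ms minimum
separation between spikes of different units (colliding spikes are dropped
from the ground truth), as spike-sorting benchmarks customarily do:
superimposed events on one electrode are not resolvable by waveform
clustering, and within-unit overlap is already excluded by construction.

## Cohort statistics

`build_activity_table` reduces each animal × call type × context cell to
its early and late window densities (×100). `fit_activity_model` fits the
linear mixed model

```
response ~ call_type * context + (1 | animal_id)
```

via `lmer` with Satterthwaite F-tests, and — because the model is fitted on
only a few dozen cells, where asymptotic p-values are fragile — runs a
seeded within-animal permutation test alongside (1999 permutations by
default; p-value `(1 + #{permuted ≥ observed}) / (1 + N)`). For the
two-level call-type factor the statistic is the absolute difference of
level means; for the three-level context factor it is the context F from a
fixed-effects model adjusting for call type (the unadjusted between-level
statistic mixes the call-type difference into the context comparison and
loses nearly all power). The context-invariance test log-transforms the
response by default, the call-type test uses the identity scale; both are
recorded in the result. With a single animal the mixed model falls back to
a fixed-effects fit with a warning.

## File formats

Traces are 16-bit PCM mono WAV (rejecting anything else); call annotations
are tab-separated UTF-8 with columns `bird_id`, `onset_s`, `offset_s`,
`call_type` (unknown call types rejected, unsorted rows sorted with a
warning); detected events use a fixed binary record — an 8-byte `SPKREC01`
tag, then per event a little-endian 64-bit float timestamp followed by 64
little-endian signed 16-bit integers (136 bytes per record). The float and
integer widths are a declared dialect, not an inference; the tag makes the
files self-identifying, and truncated files are rejected with the offending
byte offset. Times in all files are seconds from recording start.

## Worked example

```{r, eval = FALSE}
report <- run_demo(pipeline_config(seed = 12,
                                   scenario = list(duration = 600),
                                   trace_seconds = 20,
                                   stats = list(n_animals = 3)))
print(report)
```

The demo simulates one session end to end (exchange, modulated multiunit,
regular unit, a 20 s trace segment for detection and sorting), then a small
cohort for the activity model. Trace synthesis is restricted to a segment
because a full session at 22,050 Hz is dominated by memory traffic, while
20 s already contains on the order of a thousand spikes; regularity is
classified on the full-session unit trains, since a short, overlap-laden
segment supports detection and sorting but not stable ISI statistics.

## Problem sizes and tolerances

The test suite and the acceptance script run at deliberately desk-sized
scales, chosen so every stochastic check sits far from its threshold:
kernel-recovery and ordering checks use 500 calls per type at 40 spikes/s
baseline; communication calibration uses 20-min sessions (100–200 of them);
the sorting benchmark uses ~600 spikes over 30 s at SNR 10; regularity uses
100 trains of ≥ 1000 spikes per class; the model calibration uses cohorts
of 8 animals × ~150 calls. Stochastic assertions use 3σ bands around
independently computed expectations (brute-force double loops, closed-form
moments, Monte-Carlo Poisson nulls), never tuned constants.

## Known limitations

* The 1.73 association threshold is a per-bin criterion; over ~100 tested
  bins its familywise false-positive level is high, so on unmodulated units
  it flags "association" often. The package reports the peak |z| and its
  time so users can judge effect sizes; the demo compares units by peak |z|.
* The z-scored correlogram detector inherits the same property (see above);
  the surrogate detector is the calibrated alternative.
* Whether the original analyses applied 1.73 one- or two-sidedly, and over
  which baseline, is not documented; both are parameters here.
* k-means sorting is order-stable only up to label permutation and assumes
  roughly spherical clusters in snippet space; no drift correction or
  template matching is attempted.
* Mixed-model p-values on ~33–48 cells are reported but the permutation
  companion is the primary inference tool at this scale.
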