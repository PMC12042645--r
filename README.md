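# antiphony

Call-linked premotor activity and antiphonal calling in songbirds.

Female zebra finches exchange soft contact calls — *stack* and *tet* calls —
with their partners, and extracellular multiunit recordings from the
premotor nucleus RA show firing that is time-locked to the bird's own call
onsets. `antiphony` implements the full analysis chain for such recordings,
plus a ground-truth synthetic-session generator so that every stage can be
verified without access to real data:

* **Spike pipeline** — threshold detection on continuous traces
  (4.5 × robust noise SD, MAD-based), 64-sample snippet extraction, k-means
  waveform sorting, and ISI-based regular/irregular unit classification.
* **Call-aligned activity** — PSTHs (400 × 10 ms bins over ±2 s around call
  onset), z-scored over their own window; call-association detection
  (|z| > 1.73 within ±0.5 s); spike-density windows for *early*
  (−10 to +40 ms, bins 199–203) and *late* (+250 to +500 ms, bins 225–250)
  activity; return-to-baseline duration (first sustained drop of z below 2
  after onset).
* **Communication** — cross-correlograms of two birds' call trains (±4 s,
  0.1 s bins), antiphonal-calling detection (z > 2 within ±0.5 s of zero
  lag, plus a calibrated circular-shift surrogate test), and
  answer/answered/none context labelling of every focal call within a 0.5 s
  answer window.
* **Cohort statistics** — per animal × call type × context early/late
  density tables, the mixed model
  `response ~ call_type * context + (1 | animal_id)`, and seeded
  within-animal permutation tests as a distribution-free companion.
* **Synthetic sessions** — coupled two-bird call exchanges (Poisson calling
  with dead time, probabilistic answers at bounded latency), inhomogeneous
  Poisson spike trains modulated by per-call-type kernels (pre-onset dip,
  onset burst, call-type-dependent return to baseline), gamma-renewal
  regular units, and 16-bit 22,050 Hz traces with embedded spike waveforms.
* **Formats** — 16-bit PCM mono WAV traces, TSV call-annotation tables, and
  a self-identifying binary spike-record stream (64-bit float timestamp +
  64 × int16 samples per event).

## Worked example

```r
library(antiphony)
report <- run_demo(pipeline_config(seed = 12,
                                   scenario = list(duration = 600),
                                   trace_seconds = 20,
                                   stats = list(n_animals = 3,
                                                n_permutations = 499)))
print(report)
```

```
== Synthetic session ==
  600 s, 69 focal calls, 54 partner calls (37 answers)
== Detection & sorting ==
  1075 events detected (1082 embedded); clusters: 736 spikes (irregular, CV 1.07); 339 spikes (irregular, CV 0.86)
  session units: multiunit irregular (CV 1.04); regular regular (CV 0.20)
== Call association ==
  multiunit stack: peak |z| =  7.39 associated (return to baseline 0.10 s)
  multiunit tet  : peak |z| =  4.52 associated (return to baseline 0.27 s)
  regular   stack: peak |z| =  2.34 associated (return to baseline 0.00 s)
  regular   tet  : peak |z| =  3.17 associated (return to baseline 0.00 s)
== Communication ==
  antiphonal: TRUE (peak z = 5.42 at lag 0.15 s; surrogate p = 0.005)
  contexts: 1 answer, 37 answered, 31 none
== Cohort activity model ==
  late call-type effect: +0.2081 (permutation p = 0.0020)
  early call-type permutation p = 0.8300; context permutation p = 0.7680
```

Reading the report: detection recovered 1075 of the 1082 spikes embedded in
the 20 s trace segment, and the full-session trains classify as one
irregular multiunit (ISI CV 1.04) and one regular tonic unit (CV 0.20). The
call-modulated multiunit shows strong call association (peak |z| up to 7.4)
and takes longer to return to baseline after tet calls (0.27 s) than after
stack calls (0.10 s). The regular unit's modest peak z values illustrate a
documented property of the fixed 1.73 per-bin threshold: over ~100 tested
bins it flags chance excursions, so peak |z| magnitudes — clearly separated
between the two units — carry the real information. The coupled exchange is
detected as antiphonal by both the z rule (peak z = 5.4 near zero lag) and
the surrogate test (p = 0.005), contexts partition all 69 focal calls, and
the cohort model finds the late tet excess (permutation p = 0.002) with no
spurious early or context effect.

## Layout

```
R/                  implementation (generator, IO, spike pipeline, PSTH,
                    communication, statistics, demo pipeline)
tests/testthat/     unit, property and acceptance tests (fixtures built in code)
scripts/acceptance.R  headline-quantity recomputation (see above)
vignettes/          methods vignette: models, parameters, design choices
```
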