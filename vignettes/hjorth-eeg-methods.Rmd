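---
title: "Hjorth-parameter EEG analysis: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hjorth-parameter EEG analysis: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hjortheeg)
```

## Scope and data model

This package analyzes segmented multichannel EEG: each **trial** is a
fixed-duration epoch (by default 4 s at 125 Hz, i.e. 500 samples) of 16
electrode channels in microvolts, labelled with one of eight
motor-execution task codes (`taskCodes()`): a baseline with eyes open,
closing of the left/right hand, dorsal/plantar flexion of either foot, and
the inter-task Rest condition. Trials travel as `EEGTrial` S4 objects
(electrodes × samples matrix plus metadata) and on disk as per-trial CSV
files with an `E1..E16` header, one row per sample, tied to subject/task
metadata by a manifest CSV. The acquisition chain is assumed to bandpass
the signal to 5–50 Hz; nothing in the feature code depends on that, but the
synthetic generator reproduces it.

## The Hjorth parameters

For a signal $x$ of $N$ samples with first difference
$d_i = x_{i+1} - x_i$ (and $d$'s own first difference $dd$):

$$\mathrm{Activity} = \mathrm{Var}(x), \qquad
  \mathrm{Mobility} = \sqrt{\mathrm{Var}(d)/\mathrm{Var}(x)}, \qquad
  \mathrm{Complexity} = \frac{\sqrt{\mathrm{Var}(dd)/\mathrm{Var}(d)}}
                             {\sqrt{\mathrm{Var}(d)/\mathrm{Var}(x)}}.$$

Activity is the power of the signal (µV²). Mobility is a dimensionless
per-sample mean-frequency proxy: for a sampled sinusoid of frequency $f$ at
rate $f_s$ it converges to $2\sin(\pi f/f_s)$, and the first-difference
operator bounds it by 2, attained by the Nyquist oscillation. Complexity
compares the waveform to a pure sinusoid (exactly 1 for one) and, by
Cauchy–Schwarz on the spectral moments of the difference operator, is never
below 1 for a non-degenerate signal.

### Numerical conventions

- **Variance denominator.** Printed definitions of these quantities vary
  between $1/N$ and $1/(N-1)$ conventions, sometimes inconsistently between
  the signal and difference variances. This package uses the *population*
  denominator ($1/M$ over the $M$ entries actually present) for every
  variance. A mixed convention would break two properties we assert
  exactly: quadratic scale equivariance of Activity and agreement with a
  direct transcription of the definitions; the difference between
  conventions is $O(1/N)$ and immaterial at 125–500 samples.
- **Difference vector length.** $d$ has exactly $N-1$ entries and $dd$ has
  $N-2$; all sums run over the entries present.
- **No sampling-rate scaling.** $d$ is a raw consecutive difference, so
  Mobility is per-sample and dimensionless. Converting it to Hz (via
  $f_s \cdot \mathrm{asin}(m/2)/\pi$) is left to the user.
- **Degenerate signals.** A zero-variance signal (or a signal whose first
  difference has zero variance) has undefined Mobility/Complexity. Scalar
  calls (`hjorthMobility()`, strict `hjorthTriple()`) raise an error; bulk
  mode (`windowedHjorth()`, `buildFeatureTable()`) emits the `NA` sentinel
  for the undefined entries, keeps the row, and reports the affected
  row count, so one dead channel cannot abort a dataset-scale run. The
  sentinel rows are excluded from correlation and clustering, again with
  counts reported.

### Windowed extraction

`windowedHjorth()` slides a window of `windowLength` samples (default 125,
i.e. 1 s) in steps of `hop` samples (default 25, 0.2 s) over each channel,
keeping only fully contained windows. A 500-sample trial at the defaults
yields $\lfloor(500-125)/25\rfloor + 1 = 16$ windows per electrode.
Windowed mode traces how the parameters evolve within a recording;
full-trial mode (`windowLength` = trial length) gives one triple per
channel. Published per-electrode feature series of this kind do not state
which of the two was used, so both are exposed and every output records
window and hop.

## The synthetic generator

Hjorth parameters are completely determined by a signal's second-order
(spectral) structure. The generator therefore models exactly that and no
more: channel $=$ baseline band-limited Gaussian noise over the 5–50 Hz
acquisition band $+$ (for movement tasks) an independent band-limited
Gaussian burst over a task-specific band. Band-limiting uses an order-4
Butterworth applied forward and backward (`signal::filtfilt`), matching an
acquisition-style bandpass without phase distortion; measured out-of-band
leakage is well under 1% of total power. After filtering, each component is
de-meaned and rescaled so its sample SD equals the configured amplitude
exactly — note this pins *full-trial* activity of a pure-noise channel to
`noise_sd`² exactly, while windowed activities fluctuate naturally.

Defaults (per-electrode, in `defaultSyntheticConfig()`):

| parameter | value | why |
|---|---|---|
| baseline `noise_sd` | 8 µV | puts Rest activity near 64 µV², small against movement trials |
| Rest `noise_sd`, electrodes 14–15 | 16 µV | reproduces the markedly elevated Rest amplitude on that electrode pair |
| movement `burst_sd` | 12–20 µV (task-specific) | raises variance on *all* electrodes during movement; CRH windowed activity lands in the few-hundred µV² range with mobility ≈ 0.8 and complexity ≈ 1.5 |
| burst bands | 8–24 Hz, task-specific (e.g. CRH 10–15 Hz) | mu/beta-band movement oscillations; distinct bands/amplitudes make the eight tasks separable in feature space |
| BEO `burst_sd` | 4 µV, 8–13 Hz | a mild alpha-like baseline, between Rest and movement |

These values were fixed once from the qualitative structure the analysis
assumes (movement trials more variable than Rest on every electrode;
electrodes 14–15 elevated during Rest; CRH feature ranges of roughly 0–600
µV² activity, 0.3–1.4 mobility, 1.1–3 complexity) and are a documented
default, not a fitted claim about any real recording.

**Reproducibility.** Every trial draws from a substream seeded by a
polynomial hash of (master seed, subject, task, trial index), so a trial is
bit-reproducible regardless of generation order, subjects are statistically
independent, and the caller's RNG state is untouched.

**Session schedule.** A session is 124 trials. The protocol constraint is
only that Rest follows each task; the shipped schedule — two runs of
[BEO, Rest, then each of the six movement tasks five times with Rest after
every trial] — satisfies it and hits 124, but it is a package choice and
any schedule can be configured.

**What the generator does not emulate:** 1/f background, artifacts (blinks,
EMG, line noise), volume conduction/channel correlation, non-stationarity
within a trial, and inter-subject variability. Passing recovery tests on
this generator therefore shows the pipeline is correct and sensitive under
controlled second-order structure — not that real recordings separate this
cleanly; real-data ARI will be far below the synthetic 1.0.

## Correlation, clustering and contrasts

The published analyses this package operationalizes name neither a
correlation method nor a clustering algorithm, so the minimal standard
reading is implemented and recorded in the output metadata:

- `featureCorrelation()`: Pearson correlation among the three features over
  complete rows (method configurable, recorded as an attribute). Note the
  features of band-limited noise mixtures are strongly mutually correlated
  by construction; the matrix describes the realized feature cloud, not an
  independence claim. An electrode-by-electrode correlation can be obtained
  by subsetting the feature table per electrode.
- `clusterFeatures()`: rows are canonically ordered (subject, task, trial,
  electrode, window start) so results are independent of input order;
  features are standardized per column because activity's µV² scale would
  otherwise dominate Euclidean distance; `stats::kmeans` with 10 restarts
  under a fixed seed; agreement with task labels scored by the adjusted
  Rand index (`mclust::adjustedRandIndex`). With `k` equal to the number of
  complete rows the degenerate each-row-its-own-cluster partition is
  returned directly. Fixed seed + canonical ordering makes assignments
  bit-reproducible.
- `taskContrast()`: per electrode and feature, mean difference, ratio of
  means (activity only), and Cohen's *d* with the pooled-SD denominator
  (reported `NA` when either group has fewer than two observations).
  Electrodes whose mean activity under the reference task ranks in the top
  two are flagged; with Rest as reference under the default generator these
  are electrodes 14 and 15.

## Pipeline determinism

`runSimulate()` → `runExtract()` → `runAnalyze()` write trial CSVs +
manifest, the feature CSV, and a flat key/value report. Numeric values are
printed with 17 significant digits (bit-exact round trips); sidecar
metadata carries the configuration needed to re-run each stage but no
timestamps, so repeated runs of a fixed configuration are byte-identical.
Timestamped logging is confined to stderr in the command-line wrapper.

## Validation problem sizes

The test suite and the acceptance script validate at sizes chosen to make
the asymptotic oracles tight while keeping a full run inexpensive:
analytic sinusoid checks at $n = 500$ (tolerance $10^{-3}$ on mobility,
$10^{-2}$ on complexity, reflecting $O(1/n)$ edge effects), white-noise
limits $\sqrt{2}$ and $\sqrt{3/2}$ at $n = 10^5$ (±0.01), brute-force
agreement on 1000 vectors of length ≤ 12 at $10^{-12}$ relative, spectral
confinement at $n = 4096$, label recovery with 30 trials per task, and
whole-session determinism at the full 124-trial, 16-electrode geometry.

## Known limitations

- Features are computed per channel; no spatial filtering, re-referencing
  or channel-covariance modelling.
- Windowed Hjorth estimates at 125 samples are noisy for narrowband
  signals; the default 1 s window trades variance against temporal
  resolution and can be changed per call.
- Only descriptive effect sizes are reported between tasks; no hypothesis
  testing or supervised classification is included.
- The CSV reader is deliberately strict (exactly 16 numeric columns);
  adapting other dialects is a manifest/preprocessing concern.
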