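---
title: "Methods: EDA feature extraction and two-class emotion clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EDA feature extraction and two-class emotion clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edaffect)
```

## The problem

Electrodermal activity (EDA) — skin conductance in microsiemens, driven by
sympathetic sudomotor activity — is one of the few physiological channels
that reflects emotional arousal without parasympathetic confounding. This
package implements a pipeline for deciding, from a wrist-worn EDA recording
made during a short exercise protocol, whether a participant belongs to a
"positive-dominant" or "negative-dominant" emotion class, and for scoring
how well that physiological division agrees with a self-report
questionnaire (the 12-item short-form Job-related Affective Well-being
Scale, JAWS) and with an expert's division.

The pipeline is unsupervised throughout: classes come from two-cluster
partitions of the data, never from fitted labels. Its stages are

1. **Ingestion** — E4-dialect CSV files (two header lines: start epoch,
   sampling rate; one conductance value per line at a nominal 4 Hz) plus a
   tags file of marker timestamps.
2. **Segmentation** — markers are begin/end pairs delimiting three
   exercises (60 s, 10 s, 10 s in the emulated protocol); sample windows
   are half-open `[begin, end)`.
3. **Denoising** — Symlet-4 wavelet shrinkage with the decomposition level
   capped at `min(floor(log2 n), 10)`.
4. **Tonic/phasic split** — tonic = slow baseline, phasic = residual;
   GSR (galvanic skin response) events are detected on the phasic
   derivative.
5. **Features** — a 26-name battery per segment (moments, percentiles,
   regression-line indices, entropy, GSR counts/energies).
6. **Selection** — coefficient-of-variation filter, then univariate
   two-cluster WCSS filter.
7. **Clustering** — agglomerative trees under three distances, and
   k-means; each with and without a PCA rotation.
8. **Evaluation** — accuracy, sensitivity (TPR) and specificity (TNR)
   against JAWS-derived and expert reference labels.

## Signal model and preprocessing choices

**Segmentation convention.** Sample `i` (1-based) is taken to occur at
`start_time + (i - 1)/fs`; a marker pair `(b, e)` selects samples with
`b <= t < e`. At 4 Hz a 60 s exercise is exactly 240 samples. Markers must
pair up; an odd marker count is an error rather than a guess.

**Wavelet denoising.** The decomposition level rule
`level(n) = floor(log2 n)`, capped at 10, keeps the coarsest scale
meaningful for short segments (a 40-sample exercise window supports level
5). The transform is the maximal-overlap DWT (MODWT) with the sym4 filter
bank: unlike the decimated DWT it is defined for any segment length,
reconstructs exactly, and is shift-invariant, which matters because GSR
events can fall anywhere in a window. Shrinkage is soft thresholding with
a level-dependent universal threshold: the noise scale is estimated once
from the finest detail level (median absolute deviation / 0.6745, times
sqrt(2) to undo the MODWT level-1 attenuation) and decays as `2^(-j/2)`
across levels, so the slow tonic drift held in the coarse levels is left
intact. A constant segment passes through unchanged. The wavelet family
order (sym4) is a configurable default; the shrinkage rule is the only one
implemented because the downstream features are insensitive to the exact
rule at the noise levels the generator emulates.

**Tonic/phasic split.** The default tonic estimate is the per-segment OLS
trend — the slope of that line is itself one of the features, so the two
views are consistent; a centered moving median (default window 4 s) is the
alternative for segments whose baseline is visibly nonlinear. The phasic
component is defined as the residual, so `tonic + phasic` reconstructs the
segment to machine precision by construction.

**GSR events.** An event is triggered by a strict interior local maximum
of the first difference of the phasic trace with positive value (the point
of steepest rise); plateaus credit their first sample. The event peak is
the first subsequent local maximum of the phasic trace itself (the last
sample if the trace never turns down), the amplitude is the phasic value
there, the energy its square, and events above 1.5 uS are flagged
significant. Candidates whose peak amplitude is non-positive are dropped —
they are corrections of the tonic estimate, not conductance responses. The
detector is verified against an independent run-length-encoding brute
force on hundreds of random traces.

## The feature battery

Per segment, statistics are computed on the raw samples (the denoised
segment feeds only the event detector, reflecting the stage order of the
analysis): mean, SD and variance (n−1), median and interpolated 25th/75th
percentiles, quartile deviation, min/max, 4th and 5th central moments,
skewness and non-excess kurtosis from population moments (defined as 0 for
a constant segment), RMS of the signal, total sum, base-2 Shannon entropy
of a 16-bin histogram over `[min, max]`, the OLS slope/intercept, the mean
absolute and RMS residual about that line, and the residual sign-change
count. GSR features are the event count, events per minute (rpm), summed
energy, and the count and energy of significant events. The battery has 26
names where a count of 25 is sometimes quoted for such lists: the
signal RMS and the regression RMSE are deliberately kept as two separate
features ("root mean square" vs "root mean square error" name the same
list entry ambiguously), and presets can drop either.

## Feature selection

The coefficient of variation `CV = sd/mean` is compared by absolute value
(features such as the 5th moment can have negative means) against a 50%
default threshold; ties keep. Zero-mean features have undefined CV and are
rejected. The second filter scores each surviving feature with the exact
univariate two-cluster WCSS — minimal `sum((x - cluster mean)^2)` over all
2-partitions, computed by dynamic programming over the sorted values (the
1-D optimum is contiguous) and verified against exhaustive enumeration.
Features are *not* standardized before WCSS scoring: the filter is meant
to act on raw scales, and a spread of several orders of magnitude across
features is expected. Because a WCSS threshold is a histogram-inspection
choice in the original analyses, the package requires it explicitly or —
the default — keeps the `top_k = 13` smallest-WCSS features, reproducing
the published 13-of-25 cardinality in a data-driven way. Published
per-exercise subsets are also shipped verbatim (`preset_features()`,
`paper_ex1/2/3`); the Exercise-3 list's "energy of signal" is read as the
GSR energy already in the subset.

## Clustering and evaluation

Three row distances: Euclidean, `1 − Spearman rho`, `1 − Pearson r` (the
last is our reading of a tersely described "correlation" distance; the
standard correlation distance is the only well-defined interpretation we
could adopt). Agglomerative trees use average linkage by default (the
linkage is unstated in the source analyses and their trees are not
reproduction targets; average is a robust middle ground), cut at two
clusters. k-means uses k-means++ seeding with 10 restarts and Lloyd
iterations, deterministic under the supplied seed; the lowest-inertia
restart wins, and k-means inertia is test-verified never to beat the
exhaustively enumerated best 2-partition on small instances.

Cluster labels are arbitrary, so polarity matters: `best_match` (default)
flips labels to maximize agreement with the reference — the right choice
for synthetic-recovery experiments — while `fixed` keeps the raw labels
(first participant's cluster = 0), retained because published agreement
tables can contain below-chance entries that only make sense without
relabelling. Accuracy, TPR `tp/(tp+fn)` and TNR `tn/(tn+fp)` treat label 1
as the positive class; on the negative-emotion scale label 1 means
"negative-dominant", which is recorded in the report metadata rather than
silently flipped. Metrics with an empty margin are reported as `NA`, not
coerced to 0, so degenerate clusterings stay visible.

**JAWS scoring.** `pos` and `neg` are the six-item subscale sums; the
total reverse-codes negative items (`6 − raw`), giving
`total = pos + 36 − neg`, ranges 12–60 and 6–30. This reading is forced by
the arithmetic: only reverse-coding makes the group-mean identity
`44.39 = 18.29 + 36 − 9.90` and the 12–60 range come out. Reference labels
come from exact 1-D two-means on the chosen scale; the induced threshold
is the midpoint between the clusters' facing extremes, and dichotomization
at a fixed threshold is strict (`>`), a convention that only matters for
integer thresholds. Which six items are negatively keyed is survey-version
specific and therefore user-supplied configuration (default: items 7–12).

## The synthetic cohort generator

No recordings are deposited with the original study, so the generator
defines the study-shaped conditions every test runs under: 41
participants, 4 Hz, three exercises of 60/10/10 s separated by 5 s rests,
and a latent two-class structure. Each session is
`baseline + drift * t + sum_i A_i * k(t - t_i) + noise`, clipped positive,
with `k` a unit-peak Bateman (biexponential) kernel with 0.75 s rise and
4 s decay — the standard SCR shape; event times are Poisson with per-class
rates and amplitudes lognormal with per-class medians. At the default
separation the high-arousal class fires 8 events/min at ~2 uS median
against 1 event/min at ~0.5 uS — the contrast the detector's significance
threshold is designed around; baselines are uniform on 2–6 uS, drift on
0–0.01 uS/s, and measurement noise is 0.05 uS SD, all in the range of
wrist-worn dry-electrode recordings. Questionnaire items load on a single
latent trait per participant (class means ±1.25 SD at default separation,
item-trait correlation 0.9, equal-width discretization into 1..5), a
one-factor structure consistent with subscale scoring.

What the generator does **not** emulate: motion artifacts, electrode
detachment, temperature-driven baseline shifts, SCR superposition
nonlinearity, and item-level JAWS factor structure beyond one factor.
Passing recovery tests therefore show the pipeline is correct and
well-calibrated under clean two-class conditions, not that real cohorts
will separate this cleanly.

The `separation` knob scales the class contrast symmetrically to zero (a
pure null) or beyond; recovery accuracy (k-means+PCA on Exercise-1
features, best-match polarity) is test-verified to exceed 0.9 mean over 20
study-sized cohorts at separation 1 and to sit at chance (0.5 ± Monte-Carlo
error; best-match alignment biases chance slightly above 0.5) at
separation 0.

## Numerical and degenerate-case conventions

- Constant segments: variance 0, entropy 0, skewness/kurtosis 0 by
  convention, no error.
- Residuals within `1e-10 * max|x|` of the OLS line carry no sign when
  counting crossings.
- PCA is computed by eigendecomposition of the covariance of the
  centered/scaled matrix so that all p components are returned even when
  p exceeds the participant count; component signs are fixed by making the
  largest loading positive; constant columns are dropped with a warning
  when standardizing.
- `reference_labels()` accepts a seed for interface symmetry but is
  deterministic: 1-D two-means is solved exactly by enumerating contiguous
  splits.
- Ties in the WCSS top-k rule break by column order (`ties.method =
  "first"`).

## Problem sizes

The test suite and the acceptance script run study-sized problems: 41
participants, 320 s of 4 Hz signal each, 20-seed recovery sweeps; small
property tests use 8–12-participant cohorts. These sizes were chosen
because they match the cohort the pipeline emulates while keeping every
experiment's Monte-Carlo error small relative to the margins being
asserted.

## Known limitations

- The MODWT denoiser assumes circular boundaries; segments whose endpoints
  differ sharply see mild wrap-around leakage, attenuated by the level cap.
- The linear tonic model under-fits strongly curved baselines; use
  `moving_median` there.
- Two classes are hard-wired by design; the selection and evaluation logic
  would need rework for `k > 2`.
- With `polarity = "fixed"` the reported accuracy depends on an arbitrary
  anchor (the first participant), exactly as raw clustering tables do.
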