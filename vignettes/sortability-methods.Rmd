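---
title: "Assessing spike-sorting feasibility in microneurography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing spike-sorting feasibility in microneurography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microneurography records extracellular voltage from human peripheral nerves
through a single intraneural microelectrode. The C-fibres of interest are
anatomically bundled, so one electrode picks up spikes from several fibres at
once, at signal-to-noise ratios far below what cortical multi-electrode spike
sorters assume. The *marking method* provides partial ground truth: under
low-frequency background electrical stimulation (0.125–0.25 Hz) each fibre
responds with a near-constant latency, so its spikes line up vertically when
sweeps are stacked at the stimulus onsets (the *waterfall* display). Each such
latency-locked sequence — a *track* — is the equivalent of a unit, and its
spikes can be labelled with high confidence. After additional stimuli a
fibre's conduction velocity drops transiently (*activity-dependent slowing*,
ADS): the next latencies jump up and then relax back under continued
background stimulation.

`mngsort` uses those labels to ask a question that precedes any sorting of
unlabelled activity: *is this recording sortable at all?* It quantifies, per
recording, how well a supervised classifier separates the tracks in several
waveform feature spaces, how far apart the per-track mean waveforms
(templates) are, and how badly a conventional unsupervised
PCA-plus-k-means pipeline would have done against the same labels.

## Data model and lab dialects

A `recording` holds the continuous trace, sampling rate (10 kHz or 30 kHz,
the two acquisition rates in use), background stimulus onsets, and the spike
table (time, track). Times are seconds relative to `t0`; sample `i`
(0-based) covers the half-open interval `[t0 + i/fs, t0 + (i+1)/fs)`, which
makes the window-extraction arithmetic unambiguous. On disk a recording is a
directory of `signal.csv`, `stimuli.csv`, `spikes.csv` and a `meta.json`
sidecar — a direct plain-text translation of the HDF5/NIX grouping used for
harmonized electrophysiology containers.

Two dialect corrections reflect how the source laboratories export data.
Dialect **B** (30 kHz systems) records with inverted polarity: the signal is
negated and then smoothed with a centered rolling mean. The source systems do
not publish the smoothing length, so it is a parameter (default 3 samples);
edge windows shrink rather than emit NAs. Dialect **A** (10 kHz systems)
occasionally drops short stretches during acquisition; declared gaps are
filled with zeros so that sample index and time stay consistent — the
continuity requirement of downstream array processing. Unlabelled spikes
survive I/O but are excluded from every evaluation.

## Preprocessing

* **Window**: 3 ms of context is enough for a C-fibre spike, so 30 samples
  are cut at 10 kHz and 60 at 30 kHz, centered on the sample containing the
  spike time. Windows crossing a recording boundary exclude the spike, with
  the exclusion counted.
* **Resampling**: 30-sample windows are brought onto the common 60-sample
  grid by Fourier (FFT zero-padding) resampling, the band-limited scheme;
  a pure sinusoid below Nyquist is reproduced exactly, which is the oracle
  used in the tests.
* **Derivatives**: central difference quotients, one-sided at the ends, in
  volts/sample. The second derivative is the same operator applied twice.
* **Alignment**: spikes are aligned at the maximum negative peak of the
  first derivative. The canonical target position is grid index 30 of 60
  (0-based) — the window center; ties break to the earliest index. The
  implementation re-extracts the window from the raw signal at the shifted
  center whenever the shift maps to whole raw samples and stays in bounds,
  because shifting within the window would otherwise have to invent samples
  at one edge. Where re-extraction is impossible the window is shifted on
  the 60-sample grid, padding with the *edge value* rather than zeros: a
  zero step at the boundary would inject a spurious first-derivative peak
  that can steal the alignment anchor. A circular mode exists for
  property-testing (it preserves the sample multiset exactly). Windows with
  a flat first derivative cannot be aligned and are excluded, counted
  separately from boundary exclusions, so that
  `aligned + excluded = labelled` always holds.
* **Templates**: the per-track pointwise mean of all aligned spikes.

## Feature sets

Six per-spike representations are computed (dimensions in parentheses):

| set | content |
|---|---|
| `simple` (2) | amplitude `a` = positive peak; width `w` = full width at half maximum |
| `SPDF_FV3` (3) | positive peak of the 1st derivative, positive and negative peaks of the 2nd |
| `SPDF_raw` (23) | full shape/phase/distribution feature vector |
| `W_2PCA`, `W_3PCA` (2/3) | leading PCA scores of the raw waveform, fitted per recording |
| `W_raw` (60) | the aligned voltage samples themselves |

FWHM crossings are located by linear interpolation on either side of the
peak; a spike with a non-positive peak or a missing half-crossing cannot
carry the feature and is excluded (the counting mirrors the small per-set
losses seen in real data tables). For a Gaussian pulse this estimator is
within 0.05 samples of the analytic `2*sqrt(2*ln 2)*sigma` for
`sigma >= 2`, which the tests assert.

The shape/phase/distribution catalogue is anchored at six *fundamental
points* of the aligned window. The first, P1, is the first zero-crossing of
the first derivative scanning from the window start (a sign change between
consecutive samples, exact zeros included, indexed at the first sample after
the change). Spikes without such a crossing have undefined fundamental
points and are excluded from both derivative-based sets — the full vector
and the three-feature subset share one exclusion mask by construction. The
original 24-feature catalogue is followed where its definitions are printed
with the pipeline that popularized it: feature 4 is omitted (its reference
waveform is not reproducible), and feature 8 is the mean of the squared
first-derivative amplitudes from the window start up to (but excluding) P1 —
the printed summation bounds disagree with the printed divisor, and
summing `s..P1-1` over divisor `P1-s` makes it a proper mean of squares.
Features 14, 18 and 19 are the printed extrema definitions. The remaining
19 features are not printed anywhere in the source material, so the package
defines and documents its own registry interpretation
(`spdf_feature_registry()`): *shape* features describe the first
derivative's time-domain geometry (lobe widths, areas, the pre-P1 energy),
*phase* features relate first- and second-derivative amplitudes at the
fundamental points (values, phase-plane radii and angle), and
*distribution* features are moments and extrema of the derivative amplitude
distributions. Each is a pure function, testable in isolation; ratios were
deliberately avoided in favour of differences, radii and angles so that
every feature is finite whenever the fundamental points are defined.

No feature standardization is applied before the SVM or the PCA; the
reference defaults the study relied on do not standardize either, and the
choice is exposed should users want it.

## Supervised evaluation

Per recording and feature set, a classifier is scored by stratified 5-fold
cross-validation (80/20 splits). The default is an RBF-kernel SVM with the
reference defaults stated numerically so any implementation can reproduce
them: regularization constant `C = 1`, kernel width
`gamma = 1/(d * Var(X))` with `Var(X)` the population variance of the
pooled training-matrix entries, one-vs-one multiclass, no scaling. A random
forest (500 trees) is available through the same interface. Accuracy is the
fraction of correct predictions; precision, recall and F1 are
macro-averaged (the source convention specifies macro explicitly only for
F1; the package applies it uniformly and says so). Stratification keeps the
near-balanced designs balanced within folds; fold assignment is computed
after sorting rows into a canonical order, so the report is invariant to
row permutation and deterministic given the seed (default 0).

The chance baseline is `1/k` for a k-track recording, appropriate for the
near-balanced designs the marking method produces; a majority-class
baseline is available by flag.

## Unsupervised limitation analysis

To quantify how the conventional route would fare, k-means (k-means++
initialization, 10 restarts, best total within-SS, Lloyd iterations) is run
with `k` fixed to the known number of tracks, and the partition is scored
against the labels with the adjusted Rand index, normalized mutual
information (arithmetic normalization) and the V-measure (`beta = 1`; with
arithmetic normalization NMI and V-measure coincide, and the tests assert
that identity). Fixing `k` to the truth *inflates* these indices — a blind
analysis would also have to estimate `k` — so they are upper bounds on
unsupervised performance, which is the point of the exercise. A component
sweep repeats the analysis on PCA scores for 2–8 components alongside the
cumulative explained variance.

## Template similarity

Templates are compared sample-by-sample on the aligned grid without
renormalization (MSE, MAE, RMSE), keeping RMSE in recorded-voltage units.
For recordings with more than two fibres the headline distance is the most
similar pair — a reduction that can misrepresent such recordings (a
recording can pair one very similar duo with otherwise well-separated
fibres), so the sortability table flags those rows (`pair_reduced`) instead
of pretending the comparison is fair. No distance threshold is proposed:
the distances are pre-sorting indicators, to be read next to the achieved
accuracy and the chance level.

## Cross-dataset statistics

Matched per-dataset accuracies of two feature sets are compared with the
two-sided paired Wilcoxon signed-rank test: zeros discarded, exact null
distribution for up to 25 non-zero differences without ties, normal
approximation with continuity correction otherwise. The family-wise level
follows the study convention `alpha = 0.01` (stricter than the usual 0.05,
adopted as published) with Bonferroni adjustment `alpha/n` over the `n`
pairwise comparisons; significance is strict inequality. A simulation test
confirms family-wise error control under the null.

## The synthetic generator

Real marking-method recordings cannot ship with the package, so every
evaluation path is exercised against a generator that emulates the
protocol's structure: background stimuli at 0.25 Hz; per-fibre base
latencies (150 ms, spaced 25 ms — C-fibre conduction over tens of
centimetres at ~1 m/s) with 0.1 ms jitter (tracks are near-constant);
spike shapes from a tri-lobe (negative–positive–negative) Gaussian-lobe
family resembling extracellular C-fibre spikes; additive white Gaussian
noise, default SD 0.25 V against peak amplitudes of about 1.4–4.2 V (a
moderate-quality recording); and 80 sweeps by default, matching the
320–400 s of stimulation after which a typical session has collected
80–100 labelled spikes.

Two modelling choices deserve justification:

* **ADS dynamics.** The published description constrains only that slowing
  grows roughly with the number of previously elicited spikes and recovers
  under continued background stimulation. The simplest model satisfying
  both is a linear increment per evoked spike with exponential recovery:
  `s_f <- (s_f + increment * n_extra) * exp(-dt/tau)` between sweeps,
  defaults 2 ms per spike and `tau = 30 s` — order-of-magnitude choices,
  exposed as free parameters, not fitted to anything.
* **Template morphing.** The lobe family is linear in its amplitudes, so
  the pointwise morph `(1-lambda)A + lambda B` is exact, and
  `RMSE(A, morph(lambda)) = lambda * RMSE(A, B)` exactly. This turns the
  between-template distance into a controlled generator input: recordings
  can be produced at any target distance up to the base-pair distance
  (about 1.21 V), including the distances of the two published exemplar
  recordings (1.20 and 0.21). The base shapes share their lobe geometry
  and differ in amplitudes so that the alignment anchor (the
  first-derivative minimum) falls at the same grid position along the whole
  morph path; otherwise alignment would shift the two fibres differently
  and break the exact distance control.

The generator also enforces a 3 ms overlap guard between spikes (one
analysis window), mirroring the exclusion of overlapping-spike recordings
from the study data, and attaches ground truth (aligned reference
templates, the per-sweep latency table, the full configuration) to each
recording.

**What the generator does not emulate.** Real microneurography noise is
not white: it contains mains interference residue, movement and electrode
artifacts, sympathetic bursts, and amplitude drift along a track. Spike
shapes drift slowly; the generator's are stationary. Consequently, passing
the synthetic suites shows that the pipeline's machinery is correct
(alignment recovers inserted shapes, distances recover generator inputs,
classifiers reach the separability the geometry allows, chance behaves as
chance), *not* that real recordings of a given template distance will reach
any particular accuracy. One quantified example: the template-distance
estimator is upward-biased at low SNR, because alignment errors on noisy
derivatives smear the averaged templates apart — at noise SD 0.25 a true
distance of 0.21 is estimated near 0.35, while at noise SD 0.1 recovery is
unbiased to within 0.01–0.02. Template characterization is therefore done
on good-quality (noise SD 0.1) synthetic recordings, and the bias itself is
a finding worth knowing when reading small distances from noisy real data.
Checks tied to the published per-recording clustering values (ARI 0.88 on
the three-feature subset, the 82% five-component variance, the 0.62
V-measure plateau) depend on the actual deposited feature data, which is
not bundled; the acceptance tests for them state exactly where to place the
exported CSVs and report a failure, not a silent skip, in their absence.

## Problem sizes and numerics

The test suites and the acceptance script scale the number of sweeps down
(typically 15–40 per recording, 5–20 seeds per condition) while keeping
every other generator default at its study-condition value; the per-fibre
spike counts involved (30–80) sit inside the range real sessions produce.
Numerical conventions collected in one place: float comparisons in I/O
round trips at 1e-9; alignment convergence within at most a handful of
grid shifts, else the spike is excluded; zero-variance guards return 0 for
higher moments and `gamma = 1` for a constant training matrix; k-means ties
resolve by best within-SS over restarts; ranking and pair ties break
lexicographically so reports are stable.
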