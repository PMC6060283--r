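---
title: "Permutation-entropy seizure prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-entropy seizure prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peseizr)
```

This vignette explains the science behind `peseizr`: the feature, the
classifier, the alarm logic, the evaluation, what the synthetic generator
does and does not emulate, and the decisions taken where the design was
genuinely open.

## The prediction problem

Focal seizures are preceded by a *preictal* period during which the
dynamics of intracranial EEG drift away from the seizure-free
(*interictal*) baseline. A prediction system watches a continuous
multichannel recording and must raise an alarm inside a horizon before the
onset — early enough to act on, specific enough to trust. Three indices
summarise performance: sensitivity (SS, fraction of seizures preceded by an
in-horizon alarm), false prediction rate (FPR, false alarms per recorded
hour, judged against the 0.15 h⁻¹ chance level quoted in the seizure
prediction literature), and the seizure prediction horizon (SPH, minutes
between the alarm and the onset).

## Permutation entropy

For a series $x(1..N)$, embedding vectors
$X(i) = (x(i), x(i+\lambda), \ldots, x(i+(m-1)\lambda))$ are reduced to
their *ordinal pattern*: the permutation $(j_1..j_m)$ sorting the vector
ascending, ties broken by original position (so $(5,5,5) \mapsto 123$ —
a stable sort). All $N-(m-1)\lambda$ vectors are tallied and the Shannon
entropy of the pattern distribution, in nats, is normalised by its maximum
$\ln(m!)$:

$$H = -\frac{1}{\ln(m!)}\sum_g P_g \ln P_g \in [0, 1].$$

$H$ is invariant under any strictly increasing transform of the signal
(amplifier gain, offset, monotone nonlinearity), cheap to compute, and
robust to observational noise — the properties that make it attractive as
a *single* feature per channel. Rényi ($\frac{1}{1-q}\ln\sum P_g^q$,
normalised by $\ln(m!)$), Tsallis ($\frac{1-\sum P_g^q}{q-1}$) and
min-entropy ($-\ln\max_g P_g / \ln(m!)$) variants are provided behind the
same interface. The exact generalised-entropy conventions vary across the
literature; here the standard forms are used, the Tsallis measure is
normalised by its uniform-distribution maximum $\frac{1-(m!)^{1-q}}{q-1}$
so all measures share the $[0,1]$ scale, and $q$ defaults to 2.

Key parameters, all in `entropy_config()`:

| parameter | default | meaning |
|---|---|---|
| `m` | 4 | embedding dimension (pattern length); 3–7 usual, 4 balances resolution ($4! = 24$ patterns) against the ~1280 vectors available per window |
| `lam` | 1 | embedding delay in samples |
| `window_len` | 5 s | long enough for a stable estimate, short enough for stationarity |
| `overlap` | 0 | windows are non-overlapping; a trailing partial window is discarded ($x = \lfloor L / (5 \cdot 256)\rfloor$ windows from $L$ samples) |

Windowed entropies are computed by encoding every embedding vector of a
channel once (stable ranks via pairwise comparisons, vectorised) and
tabulating the integer codes per window, so a six-channel hour costs well
under a second.

## From windows to a decision

**Labelling.** A window is preictal when its half-open interval intersects
$[\text{onset} - \text{horizon}, \text{onset})$; intersection rather than
containment maximises the scarce positive class. The horizon defaults to
50 min — the labelling convention used with the Freiburg database.
Windows inside the ictal interval or within a 30-min post-ictal margin are
excluded: the classifier should learn the preictal/interictal contrast,
not seizure or recovery dynamics.

**Splitting.** Evaluation is leave-one-seizure-out; patients need at least
three seizures so that two or more always remain for training. Training
data are the other seizures' preictal windows plus a pool of interictal
windows from seizure-free recordings (any recorded alongside the test
seizure are dropped — no leakage by provenance). The majority class is
undersampled to the minority count with a fixed seed.

**Classifier.** An RBF-kernel SVM, grid-searched over $(C, g)$ by
label-stratified 6-fold cross-validation maximising accuracy (the CV
criterion is not uniquely dictated by the problem; accuracy on the
balanced set is the natural choice). Ties break towards smaller $C$, then
smaller $g$ — the least complex model among equals. The classifier sits
behind a fit/predict contract so alternatives can be swapped without
touching the pipeline.

**Firing power.** Window-wise labels are far too noisy to alarm on
directly. The two-step scheme counts preictal labels in 2-min short
windows (24 labels), calls a short window preictal when the count reaches
$p \in \{1..12\}$, then partitions short windows into consecutive
non-overlapping triples (6-min long windows) and alarms when at least
$k \in \{1,2,3\}$ of a triple are preictal. Long windows are fixed
partitions, not sliding: alarms are evaluated at long-window boundaries
and timestamped at the window's start. The one-step comparator thresholds
a single 6-min window (72 labels) directly; its candidate thresholds
$\{3, 6, \ldots, 36\}$ scale the two-step $p$ range to the three-times
longer window, keeping the candidate count and fractional coverage equal.

**Refractory period.** After an alarm, further alarms are suppressed for
one horizon (default 50 min, configurable including off). Without it, FPR
is ill-defined over long preictal-like stretches: one misclassified
episode would otherwise be counted as many false alarms.

**Scoring.** A seizure counts as predicted iff at least one alarm lies in
its preictal interval; SPH is measured to the *first* such alarm, and
later in-horizon alarms are neither hits nor false alarms. Every alarm
outside all preictal intervals is false. $N_T$ in FPR is the **total**
recording time (interictal + preictal) — the simple ratio definition —
although interictal-only time is also common in the literature; values
are therefore conservative relative to that alternative.

**Model selection.** Over the candidate set, FPRs are normalised to
$\mathrm{fprn} = \mathrm{fpr}/\mathrm{fpr}_{max} \cdot 100$ (all-zero sets
map to zero) and the candidate minimising
$ed = \sqrt{(\mathrm{SS}\% - 100)^2 + \mathrm{fprn}^2}$ wins; ties prefer
higher sensitivity, then lower raw FPR. Two further choices were open:

* *Where selection happens.* Selecting $(p, k)$ on the test seizure
  itself is optimistically biased. The default (`selection =
  "validation"`) scores candidates on one held-out *training* seizure's
  continuous record, labelled by an inner model trained without it (the
  inner model reuses the grid-searched $(C, g)$; with the 3-seizure
  minimum, a fully separate validation seizure would leave a single
  seizure for inner training). `selection = "test"` reproduces in-sample
  selection.
* *Residual ties.* On clean selection data many candidates tie at
  $ed = 0$. Candidate grids are enumerated conservative-first (largest
  $p$, $k$, threshold first), so full ties resolve to the candidate
  demanding the most evidence per alarm. The asymmetry is deliberate: an
  over-permissive winner risks a false alarm whose refractory period can
  swallow the true alarm (costing both SS and FPR), whereas an
  over-conservative winner merely shortens SPH.

## The synthetic generator

`generate_recording()` emulates exactly the statistical structure the
pipeline consumes — the per-window entropy levels of the three regimes —
not physiological EEG (no spikes, no artifacts, no 1/f spectrum, no
inter-channel coupling). Each channel is AR(1) noise ($\varphi = 0.95$,
unit innovation SD) plus three sinusoids with regime envelopes:

| regime | recipe | window PE (m = 4, λ = 1) |
|---|---|---|
| interictal | 10 Hz, amplitude 5.4, constant | ≈ 0.775 (target 0.75–0.8) |
| preictal | + 5 Hz ramped linearly 0 → 25 across the horizon | declines to ≈ 0.53 (target 0.5–0.75) |
| ictal | + 3 Hz, amplitude 60, 2-s attack, 60-s release | ≈ 0.44 (sharp drop) |

The amplitudes were tuned once on a pilot generation so windowed PE meets
those targets, then frozen. The linear preictal ramp makes early preictal
windows nearly indistinguishable from baseline — deliberately, so the
classifier faces a realistic gradual transition and the firing-power
stage has actual work to do. Generation is bit-reproducible given the
seed.

The default test patient (`synthetic_patient()`) is three one-hour
six-channel seizure recordings (onset at 3300 s, 60-s seizure, so the
50-min preictal interval spans 300–3300 s) plus one interictal hour —
small enough that the complete leave-one-seizure-out experiment, grid
search included, runs in well under a minute, while exercising every
stage at the database's native rates. The experiment-level defaults
(`C_grid = 2^{-1,1,3,5}`, `g_grid = 2^{-7,-5,-3,-1}`) are a compact
version of the standard exponential grids, adequate because the synthetic
classes are well separated; real data would warrant the full
`2^seq(-5, 15, 2)` × `2^seq(-15, 3, 2)` grids, available via
`grid_search_cv()` defaults.

What passing the end-to-end test shows: the pipeline's plumbing, label
bookkeeping, alarm logic, selection machinery and determinism. What it
does not show: that permutation entropy separates preictal from
interictal states in *clinical* iEEG — that claim can only be assessed on
real recordings.

## Numerical and degenerate-input conventions

* Natural logarithms throughout; entropies are reported normalised, never
  in raw nats, and clamped to $[0,1]$ against floating-point spill.
* Ties in ordinal patterns follow the stable rule (earlier index first);
  patterns serialise as 1-based index sequences such as `"3,1,2"`.
* A series shorter than $(m-1)\lambda + 1$ samples, an empty pattern
  distribution, $q = 1$ for Tsallis/Rényi, single-class training data,
  mismatched feature dimensionality, annotations outside the record, and
  overlapping seizures are all rejected with validation errors rather
  than silently coerced.
* Resampling preserves duration to within one output sample
  ($\lfloor n \cdot fs'/fs \rfloor$ samples); the 50-Hz notch is a
  zero-phase second-order band-reject (1 Hz default bandwidth) so
  filtering cannot shift onset-relative timing.
* All randomness (undersampling, CV folds, synthetic generation) flows
  from explicit seeds; two runs with the same configuration are
  identical.

## Known limitations

* The six analysis channels are configuration, not inference: with
  real 128-channel recordings the user must supply the channel ids
  (conventionally three focal, three extra-focal).
* FPR uses total record time (see above); compare across studies with
  care.
* Candidate selection on one validation seizure estimates each
  candidate's FPR from a single hour; the conservative tie-break
  compensates, but more interictal validation data would discriminate
  candidates better.
* The EDF reader covers continuous EDF/EDF+ recordings with one common
  sampling rate; discontinuous EDF+D files are out of scope.
* Streaming/real-time operation is out of scope; the pipeline is
  batch-oriented.
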