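---
title: "Temporal combination pattern optimization for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal combination pattern optimization for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempocsp)
```

## The problem

Two-class motor-imagery BCIs decode which limb movement a user imagines
from sensorimotor EEG. The workhorse feature extractor is the common
spatial pattern (CSP): given band-pass-filtered trials of two classes, CSP
finds spatial filters `w` that maximize the variance of one class relative
to the other, and the log-variances of the filtered signal are the
classification features. CSP's effectiveness depends strongly on *which
time window* relative to the imagery cue is analyzed — yet that window is
conventionally fixed by hand (e.g. 2–6 s from trial start). Event-related
desynchronization (ERD), the power drop that carries the class
information, is intermittent and its timing varies across users, so a
single fixed window is rarely optimal.

This package replaces the fixed window with a *temporal combination*: each
trial is decomposed into five overlapping cue-locked windows, CSP features
are extracted per window, concatenated, and a feature-selection step picks
the best combination of feature pairs across windows before SVM
classification.

## The pipeline

1. **Segmentation.** Window `i` spans `[t0·(i−1), 2 + t0·(i−1)]` s after
   cue onset, `i = 1..5`, with window length fixed at 2 s. `t0 = 0.5` s
   suits a 4-s imagery period (the five windows then tile cue+0 to cue+4 s);
   `t0 = 0.25` s suits 3–3.5-s periods. All windows are half-open sample
   intervals `[start, end)` with 0-based starts rounded to the nearest
   sample, so `t0 = 2` would tile without overlap or gap.
2. **Band-pass filtering.** A 3rd-order Butterworth band-pass, 8–30 Hz,
   covering the mu and beta rhythms that express ERD.
3. **CSP per segment.** With `m = 2` filters per eigenvalue extreme, each
   segment yields `2m = 4` log-variance features; five segments give a
   20-column feature table. Within a segment, filter `j` pairs with filter
   `2m+1−j` — the largest-eigenvalue filter with the smallest — because a
   variance increase for one class mirrors a decrease for the other.
4. **Selection.** One of four methods reduces the 20 columns to `k = 4`
   (two CSP pairs): MUIN (Parzen-window mutual information ranking), LASSO
   (`argmin ‖y − Fβ‖₂² + λ‖β‖₁`, ranking by contribution degree
   `CD_j = |β_j|`), PCA (top-`k` principal axes; a transform, not a
   subset), or SWLDA (forward/backward partial-F stepwise regression,
   entry at `p < 0.1`, removal at `p > 0.15`, capped at `k`).
   `k = 4` matches the feature count of the fixed-window CSP comparator
   (`selector = "none"`), keeping the comparison dimension-fair.
5. **Classification.** An SVM (via LIBSVM through `e1071`). The kernel and
   cost are unreported dimensions in this family of methods; the default
   is linear with `C = 1` and training-split standardization, because four
   log-variance features are near-linearly separable and a linear default
   removes a tuning dimension. Both are configurable.
6. **Evaluation.** Repeated stratified 10-fold cross-validation (default
   10×10). Every stage that learns from data — CSP, selector, SVM — is fit
   inside the training split only. Filtering and windowing are per-trial
   operations and are precomputed once; no information crosses trials.

## Numerical and design choices

**Zero-phase filtering.** The Butterworth filter is applied
forward–backward (`signal::filtfilt`), so it has zero phase: group delay
would shift the short windows, while CSP consumes variance, which is
invariant to the squared magnitude response. By default each full trial is
filtered once and windows are sliced afterwards, so 2-s windows carry no
filter start-up transient; `filter_mode = "segment"` filters each sliced
window separately for users who want strictly windowed processing. The
3rd-order design at 8–30 Hz / 100 Hz is numerically well-conditioned in
transfer-function form; outputs are checked finite.

**CSP conventions.** Class covariances are averages of per-trial
trace-normalized spatial covariances (each trial contributes equally
regardless of broadband power). The fit whitens the composite covariance
and eigendecomposes the whitened class-1 covariance; every filter
satisfies `wᵀC₁w + wᵀC₂w = 1` and the eigenvalues (class-1 variance
shares) are sorted descending in `[0, 1]`. Eigenvector signs are fixed by
making each filter's largest-magnitude coefficient positive; equal
eigenvalues keep the eigensolver's stable order (documented as
non-unique). Rank-deficient composite covariances raise an error
suggesting the optional shrinkage `C ← (1−γ)C + γ(tr C/c)I`; the default
is `γ = 0` since no regularization is part of the base method. Features
are `log(var(wᵀE))` as such; the conventional normalized variant
`log(var/Σvar)` is available as `normalize = TRUE`.

**MUIN bandwidth.** The Parzen kernel bandwidth follows Silverman's rule
per class, `h = (4/(3 n_ω))^{1/5} σ_ω`, with `σ_ω` the class-conditional
standard deviation of the *feature*. Reading σ as the standard deviation
of the label vector instead would make the bandwidth independent of the
feature being scored, which is untenable; the per-class-feature reading is
the standard one for this estimator family. Conditional entropy is the
empirical mean over training trials of `−Σ_ω p(ω|v_i) log₂ p(ω|v_i)`, and
the estimate is clipped to `[0, H(ω)]`.

**LASSO.** Solved by cyclic coordinate descent on the centered problem
(intercept absorbed), so `λ_max = max_j |2 f_jᵀ(y − ȳ)|` is the exact
full-shrinkage bound. The λ grid is geometric, 50 points from `λ_max` down
to `10⁻⁴ λ_max`, walked downward until at least `k` coefficients are
nonzero (warm-started between grid points). The solver is validated
against the orthonormal-design soft-threshold closed form, the
least-squares limit at `λ = 0`, and an exact KKT active-set solution on
general correlated designs.

**Pair completion.** MUIN, LASSO and SWLDA selections must be closed under
the CSP pairing. All three use the same deterministic walk: traverse the
method's ranking, adding each new column together with its partner, until
exactly `k` columns are held; ties break toward the lower column index.
Because the pairing is an involution the set grows two at a time, so the
walk cannot overshoot an even `k`. For SWLDA the pairing is enforced
*after* the stepwise loop (the stepwise steps themselves are
pair-agnostic), ranked by entry significance so the least significant
entries are dropped first if pairing would overflow `k`. PCA ignores
labels and the pairing constraint — a pairing rule has no meaning for
dense orthonormal components; for time-window bookkeeping each component
is attributed to the segment of its largest-magnitude loading, an
interpretation recorded as such.

**SWLDA termination.** The loop stops when `|S| = k` or when neither a
forward nor a backward move is legal; a state-repeat guard breaks
enter/remove cycles. `meta$termination` records which condition fired, and
a selection where nothing ever passed entry is returned empty and flagged
(`meta$empty`) rather than silently substituted. Partial-F p-values use
1 and `n − q − 1` degrees of freedom with `q` the size of the larger model.

**ERSP.** `ERSP(f,t) = (1/N) Σᵢ Gᵢ(f,t)²` with `Gᵢ` a short-time Fourier
magnitude — 0.5-s Hann window, 90 % overlap by default, both configurable.
No baseline normalization is applied by default because the definition has
none; a `relative` mode (divide by mean pre-cue power per frequency) is
available for ERD visualization and the mode is recorded in the output.
The estimator satisfies exact laws used as tests: quadratic amplitude
scaling, additivity over trial-set unions, and non-negativity.

## The synthetic ERD generator

Real competition recordings cannot be bundled, so the package generates
two-class lateralized ERD data with known structure: every channel carries
a band-limited sinusoidal rhythm (default alpha, 8–12 Hz, 10 µV) with
per-trial random phase and in-band frequency jitter, over i.i.d. Gaussian
noise (default 2 µV); on the ERD channels of the trial's class (defaults:
channel 3 for class 1, channel 6 for class 2 — C3/C4 analogues) the rhythm
amplitude is multiplied by `1 − depth` during the active windows (default
the first 3 s of imagery, `depth = 0.8`), with 100-ms raised-cosine ramps
so the gating does not ring through the band-pass filter. The single
sinusoid (rather than filtered noise) makes band power and channel
variance closed-form: pre-cue channel variance is `noise_sd² + A²/2`,
which the tests check. A label-permuted variant destroys all label–signal
association for chance-level controls, and an optional mixing matrix can
induce spatial correlation.

What this emulates — and what it does not: lateralized band-limited power
attenuation with controllable depth, timing and SNR. It does *not* emulate
1/f spectra, artifacts, volume conduction, or trial-to-trial ERD
variability ("intermittent" ERD). Consequences: decoding accuracies here
are upper-bound-like (the default study reaches ~99–100 % for all
methods), and because the deterministic ERD makes windows 1–3 nearly
perfectly correlated (feature correlation ≈ 0.998), the *complementary*
selectors (LASSO, SWLDA) typically select one early pair plus one late,
partially-overlapping pair, whereas marginal-ranking MUIN selects early
windows exclusively. On real data with unstable ERD the early windows
decorrelate and all selectors spread more informatively. Passing tests on
this generator therefore validate the machinery and its contracts, not
real-data effect sizes.

## Problem sizes and reproducibility

The test suite and the acceptance script use a 200-trial, 8-channel,
100-Hz study (100 trials per class) with 2×10-fold cross-validation for
the selector comparisons, and the full 10×10-fold protocol for the
partition-accounting checks — sizes chosen to exercise every code path at
the scale of a single competition calibration run while keeping a full
suite run in minutes. All generation and cross-validation is
bitwise-reproducible given the seeds carried in `synth_config` and
`pipeline_config$cv`; persisted reports embed the seed and a config hash.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_trials_per_class = 50, seed = 7)
ts <- generate_mi_trialset(cfg)

report <- cross_validate(ts, pipeline_config(
  selector = "lasso", cv = list(n_repeats = 2, n_folds = 10, seed = 1)))
report
segment_usage(report)

baseline <- cross_validate(ts, pipeline_config(
  selector = "none", cv = list(n_repeats = 2, n_folds = 10, seed = 1)))
compare_methods(list(csp = baseline, lasso = report), comparator = "csp")
```

## Known limitations

- Two classes only; multi-class CSP extensions and filter-bank (multiple
  frequency band) variants are out of scope.
- The competition archives are not bundled and no network access is ever
  attempted; `epoch_continuous()`/`load_trialset()` accept
  continuous-plus-markers data that users download themselves.
- PCA's window attribution (dominant loading) is an interpretation; dense
  components have no unique window.
- The SWLDA stepwise path is greedy; ties and near-collinear candidates
  can make the trajectory sensitive to small perturbations, which is
  inherent to the method.
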