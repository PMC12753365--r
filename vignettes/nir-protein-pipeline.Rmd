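---
title: "Predicting maize protein from NIR spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting maize protein from NIR spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Short-wave near-infrared (NIR) absorbance spectra of maize powder in the
940–1660 nm window carry overtone bands of the X–H bonds that make up grain
constituents: the N–H second overtone near 1000 nm and N–H/C–H combination
bands in the 1500–1600 nm region track protein, the C–H second overtone
near 1206 nm tracks starch, and the O–H first overtone near 1460 nm tracks
moisture. In the Beer–Lambert regime absorbance is approximately linear in
constituent concentration, so protein content (% dry basis) can be
calibrated against spectra by multivariate regression — provided the
physical nuisances of powder measurement (multiplicative scatter from
particle size and packing, additive baseline offsets and drift, detector
noise) are dealt with.

`nirmaize` implements the full calibration pipeline: scatter-correcting
preprocessing, SPXY sample-set partitioning, PLSR and SVR calibration,
four wavelength-selection algorithms, and R/RMSE/RPD evaluation, plus a
synthetic spectrum generator with known ground truth so every stage can be
validated at desk scale.

# Preprocessing

Eight schemes are supported, four primitives and four compositions
(`standard_plans()`): MSC, SNV, first derivative (D1), Savitzky–Golay
smoothing (SG), and `d1+snv`, `d1+msc`, `sg+snv`, `sg+msc`. In the
compositions the derivative or smoothing runs first; applying scatter
correction afterwards keeps derivative-amplified noise out of the
corrected spectra.

* **MSC** regresses each spectrum on a reference (the calibration-set mean),
  `R_i = Gain_i · R̄ + Bias_i`, and reports `(R_i − Bias_i)/Gain_i`. The
  reference is fitted on calibration spectra only and reused for the
  validation set — fitting on "all samples", as is sometimes done, leaks
  held-out information into the correction.
* **SNV** standardizes each spectrum to mean 0, SD 1 (sample SD, divisor
  n−1, so `snv([1,2,3]) = [−1,0,1]` exactly).
* **D1** is a finite central difference with one-sided differences at the
  two endpoints. It is deliberately *not* a Savitzky–Golay derivative: the
  scheme list treats D1 and SG as distinct primitives that are composed
  separately. Keeping the full grid (rather than dropping edge channels)
  keeps channel indices comparable across schemes, which wavelength
  selection relies on.
* **SG** (window 7, order 2 by default) fits a local polynomial in a moving
  window. At the edges the window shrinks to the available one-sided
  channels; the polynomial order is capped at one less than the number of
  points in the shrunk window, so polynomials up to the order are
  reproduced exactly everywhere and an interpolating configuration
  (order ≥ window − 1) is the identity.

# SPXY partitioning

Samples are split 2:1 into calibration and validation (60/30 at n = 90) by
the standard SPXY procedure: the joint distance
`d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)` (Euclidean on spectra,
absolute difference on protein) seeds the calibration set with the
farthest pair, then greedily adds the sample with the largest minimum
distance to the set. The algorithm is deterministic; ties break toward the
lowest index after a lexicographic sort of sample ids, which makes the
split invariant to row order. Distances are computed on the spectra as
loaded (partitioning precedes the preprocessing comparison); a corrected
matrix can be passed instead if desired.

One caveat worth knowing: SPXY improves but does not guarantee coverage of
the response range. A sample with extreme protein whose spectrum is
already well covered contributes little maximin score and can end up in
validation. On default synthetic data the validation protein range nests
strictly inside the calibration range in roughly three quarters of seeds —
well above the ≈44% a random 60/30 split achieves, but not a certainty,
and the test suite asserts only the advantage over random splitting.

# Calibration models

**PLSR** is fitted by NIPALS on mean-centered data (channels share
absorbance units, so no variance scaling). For a univariate response each
component is extracted in closed form — the weight vector is the
normalized X–y covariance — followed by deflation; extraction stops early
if residual covariance falls below 1e-10. The regression vector is folded
back to channel space, `b = W(P'W)^{-1}q`, so prediction is a single
affine map, and the first *a* columns of the factor structures are exactly
the *a*-component fit, which makes the cross-validated component search
(1–20, shared 5-fold plan, ties to the smaller count) a single fit per
fold. The zero-component predict-the-mean baseline is reported alongside
but never selected. Five folds is a conventional choice for a 60-sample
calibration set; the fold count and shuffle seed live in `cv_plan()`.

**SVR** (linear and RBF) delegates the epsilon-insensitive solver to
`e1071` and owns everything around it: channels are standardized with
calibration statistics (SVMs are scale-sensitive where PLSR is not), and
the canonical grids — C ∈ {0.01, 0.1, 1, 10, 100}, gamma ∈ {1e-4 … 10}
(RBF only), epsilon ∈ {0.01, 0.05, 0.1, 0.2}; 20 and 120 combinations —
are searched exhaustively by RMSECV under the same fold plan. An opt-in
`extended_c` flag appends C = 1000, which appears in some published result
tables but exceeds the stated grid; it is off by default and flagged
non-canonical.

# Wavelength selection

All four methods return a `selection_result` with full-length importance
scores (unselected channels keep their computed score, not zero) so
importance profiles can be exported and plotted.

* **PLSRC** ranks channels by |b| of the CV-optimal full-spectrum PLSR and
  picks the top-k set minimizing RMSECV of a PLSR refit over
  k ∈ {5, 10, …, min(60, p)}.
* **CARS** runs (default 50) Monte-Carlo rounds: fit PLSR on a random 80%
  sample draw, enforce the exponentially decreasing retention schedule
  `r_i = a·e^{−k i}` pinned so run 1 keeps all p channels and the final
  run keeps 2, then resample within the kept set with probability
  proportional to normalized |b|. The retained set with the lowest RMSECV
  wins; importance is per-channel selection frequency. The retained count
  never increases across runs and a two-channel floor is enforced.
* **SPA** builds a deterministic chain from every starting channel by
  repeatedly choosing the column with the largest residual norm after
  orthogonal projection onto the span of the chosen ones (exact
  duplicates are annihilated and cannot be selected twice). Every (start,
  length) pair is scored by the RMSECV of a plain multiple linear
  regression; ties prefer fewer channels, then the lower start. The
  reported model is a PLSR refit on the winning set, the conventional
  pairing.
* **UVE** appends p artificial noise channels (uniform draws scaled by
  1e-10 — the stability statistic is scale-free, so the scale only
  guarantees the noise cannot help prediction), refits PLSR once per
  leave-one-out resample, computes `c_j = mean(b_j)/sd(b_j)`, and keeps
  real channels whose |c| exceeds the largest noise-channel |c| — the
  strictest canonical cutoff, under which artificial channels are excluded
  by construction.

A point about what selection *should* find: all protein bands are driven
by the same concentration, so their channels are mutually collinear by
construction. Frequency-based selectors (CARS, UVE) happily retain several
bands; SPA, whose objective is minimal collinearity, deliberately keeps
one strong protein band plus channels that correct interference elsewhere,
and should not be expected to cover every protein band. On default
synthetic data SPA reliably covers the 1000 nm band and rarely the
overlapping 1515/1582 nm pair — that is the algorithm working as designed,
not a recovery failure.

# Evaluation

`pearson_r`, `rmse` (divisor m, residuals against predictions) and
`rpd = SD/RMSEP` (SD = sample SD of the validation reference values, so
every report satisfies RPD·RMSE_p = SD identically). An RPD above 2 is the
conventional threshold for a usable quantitative NIR model. One deviation
is documented here: a common formula rendering of RMSE subtracts the
reference mean rather than the prediction, which would compute an SD, not
an error; the implementation uses prediction residuals throughout, which
is what reported calibration/validation tables actually contain.
`run_experiment()` shares one SPXY split and one CV plan across every
preprocessing × model (× selection) cell, records per-cell failures
without aborting, and reports wall time (median of repeated fit+predict)
separately from the metric columns, which are deterministic given the
grid seed.

# The synthetic generator

`generate_dataset()` emulates a 90-sample maize powder study: three
replicate spectra per sample (averaged, as replicate probe placements on
a powder cell are in practice), protein uniform on 8.43–11.25% (mean
9.84%), and Gaussian absorption bands — protein at 1000/1515/1582 nm,
starch at 1206 nm, moisture at 1460 nm — on a 128-channel grid (a typical
pixel count for short-wave NIR array spectrometers; the span and count are
configurable). Each replicate sees a multiplicative gain (SD 0.12 about
1), an additive offset (SD 0.05 AU), a linear baseline drift (SD 0.10 AU
across the grid) and white channel noise (SD 0.002 AU, a conservative
figure for array instruments); all draws are per replicate, since scatter
arises from repacking between measurement points, and the whole dataset is
deterministic given the seed.

Two design choices deserve explanation:

* **Mass closure.** Starch concentration is drawn as an independent
  uniform component *minus* the sample's protein deviation from the range
  midpoint (coefficient −1; moisture is independent; coefficients are
  configurable). Constituent fractions in a real powder sum to roughly
  100%, and this coupling matters: with fully independent constituents,
  scatter-normalizing corrections (MSC/SNV), which can only preserve
  composition ratios, destroy the protein signal — linear recovery caps
  near R ≈ 0.8 even on noiseless data — which is the opposite of how these
  corrections behave on real powder spectra. With closure the corrected
  spectra retain the protein information, as they do in practice.
* **Noise/scatter magnitudes.** The defaults were set once so that the
  pipeline operates in the regime reported for real maize powder data:
  full-spectrum PLSR validation R in the mid-0.9s, the 1D+MSC → PLSR →
  SPA pipeline reaching R_p ≈ 0.93 and RPD ≈ 2.8 with ~10–15% of channels
  retained. They live in `synthetic_config()`, not in code.

What the generator does *not* emulate: particle-size-dependent
(wavelength-dependent) scatter, instrument line-shape and stray light,
non-Beer–Lambert saturation, water-activity band shifts, and the closure
structure of a real ~10-constituent grain matrix. Passing recovery tests
on this generator therefore demonstrates that the algorithms do what they
claim on data with the assumed structure — not that a real instrument
calibration will reach the same numbers.

# Numerical choices and degenerate inputs

* NIPALS stops a component when residual covariance < 1e-10; a zero-
  covariance first component is an error.
* MSC errors on a constant (zero-variance) reference and on per-spectrum
  gains below 1e-12, naming the offending sample; SNV errors on constant
  spectra.
* D1 requires a uniform grid (relative spacing tolerance 1e-6).
* SPA truncates a chain when all residual norms fall below 1e-12 (rank
  collapse); RMSECV ties break toward fewer channels, then lower start
  index.
* UVE treats a zero coefficient SD as infinite stability, with a warning;
  if no channel beats the noise cutoff the single most stable channel is
  kept, with a warning.
* SPXY drops a degenerate distance term (all-identical spectra or
  responses) with a warning rather than dividing by zero.
* Constant responses make `fit_svr_grid` return a constant predictor with
  a warning instead of failing the grid.

# Problem sizes used in the test suite

The suite validates on 90-sample, 128-channel synthetic datasets — the
scale the generator emulates — with 20-seed repetitions for the stochastic
recovery claims, 100 seeds for split-coverage statistics, and small
exhaustively checkable instances (n ≤ 10 channels) wherever an independent
oracle (OLS, QR-based exhaustive projection, double-loop greedy SPXY) is
compared against the implementation.
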