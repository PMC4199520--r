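---
title: "Methods: wavelet-compressed FAIMS profiles under nested LOO-CV"
author: "faimsdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-compressed FAIMS profiles under nested LOO-CV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faimsdx)
```

## The problem

Field asymmetric ion mobility spectrometry (FAIMS) of urine headspace
measures a two-dimensional ion-current map over the instrument's dispersion
field (percent of maximum field) and compensation voltage (volts). Gut
fermentation products — volatile organic compounds (VOCs) — appear as
localized peaks in this plane, and a disease state that perturbs gut
fermentation can shift the pattern. `faimsdx` implements a complete,
testable pipeline for asking whether such maps discriminate two patient
groups — here coeliac disease (CD) against diarrhoea-predominant irritable
bowel syndrome (D-IBS) — at pilot-cohort scale (tens of patients), where
the entire statistical difficulty is that the feature space (tens of
thousands of pixels) dwarfs the sample size.

The companion screen works on GC-MS chromatograms of the same specimens:
peaks above an intensity threshold are binned by retention time across
samples, and bins present in (nearly) every sample of one class and in no
sample of the other are flagged as candidate class-unique markers.

## Feature pipeline

Each patient contributes up to three replicate scan pairs (one matrix per
ion polarity). The pipeline is:

1. **Replicate aggregation.** Replicates are flattened (positive-polarity
   matrix row-major, then negative) and averaged element-wise, one vector
   per patient. Averaging at the patient level is deliberate: the patient,
   not the scan, is the statistical unit, so replicates can never straddle
   a cross-validation split.
2. **Daubechies wavelet compression.** The vector is zero-padded to the
   next power of two and transformed with a periodized orthonormal
   Daubechies filter bank (default order 4, full decomposition depth). The
   padded analysis operator is exactly orthonormal: the transform is
   linear, preserves the Euclidean norm, and is inverted to machine
   precision by `dwt_inverse()`. Localized peaks compress into few large
   coefficients, which is precisely the structure the later sparse
   selection exploits. The index map records each coefficient's level,
   band and position, and the original length, so padding is identifiable
   and carries no signal.

   Only the periodized boundary is offered. A truncated zero-extension
   convolution variant was considered and rejected: it loses orthonormality
   (and with it energy conservation and the clean inverse), while
   zero-padding to a power of two already handles arbitrary grid sizes.
3. **Variance filtering.** Coefficients whose variance across the
   *training* patients falls below a cutoff are discarded as
   noise-dominated. The cutoff can be absolute or a training-variance
   quantile; the default keeps the top 5% of coefficients by variance.
   The filter is label-blind but data-dependent, so it is refitted inside
   every cross-validation fold.
4. **Rank-sum feature ranking.** Surviving coefficients are ranked by
   two-sided Wilcoxon rank-sum p-value between the classes and the `k`
   smallest are kept (default `k = 30`; ties broken by ascending
   coefficient index for determinism). The implementation uses the exact
   null distribution of the Mann–Whitney statistic for pooled sizes up to
   12 without ties, and the tie-corrected, continuity-corrected normal
   approximation otherwise.
5. **Classification.** Three families behind one fit/predict contract,
   with coeliac disease coded as the positive class:
   * *Sparse logistic regression* — elastic-net-penalized logistic
     regression (`glmnet`), mixing parameter 0.5, penalty strength chosen
     by internal 5-fold cross-validation **on the training fold only**.
     Observations are weighted inversely to their class frequency (see
     below). Internal folds are class-stratified and derived from a
     label-independent permutation, which makes a label swap map fitted
     probabilities exactly to their complements.
   * *Random forest* — 500 trees (`randomForest`), class vote fractions as
     probabilities.
   * *Support vector machine* — linear kernel, cost 1 (`e1071`); the
     held-out score is the signed margin mapped through the logistic
     function, a monotone transform that leaves ROC ranking identical to
     the margin itself.

### Why balanced class weights

Under leave-one-out cross-validation the training base rate is mechanically
anti-correlated with the held-out label: holding out a case leaves 26/46
cases, holding out a control leaves 27/46. A regularized logistic model
that shrinks to the intercept then predicts exactly this base rate, ranking
every held-out control above every held-out case — a null cohort scores an
AUC near 0, not 0.5. Weighting observations inversely to class frequency
makes the no-information prediction 0.5 in every fold and restores the
chance-level null. This is a property of the evaluation design, not of the
data, and the package treats it as a default (`weights = "balanced"` in
`classifier_spec()`; `"none"` restores unweighted fits).

## Leave-one-out cross-validation and the nesting rule

`run_loo_cv()` predicts each patient from a model that has never seen that
patient: the variance filter, the rank-sum ranking, the internal penalty
tuning and the classifier fit are all recomputed per fold on the other
n − 1 patients. Replicate aggregation and the wavelet transform are
per-sample deterministic maps, so they are computed once up front — they
cannot transport information between patients.

The package also exposes `nested = FALSE`, which deliberately fits the
variance filter and feature ranking once on *all* patients before the
loop. This exists purely as a diagnostic: on null cohorts the leaky
variant's mean held-out AUC rises well above chance (about 0.64 in the
packaged acceptance checks versus about 0.48 nested), which is the
selection-bias artifact the nesting rule exists to prevent. It should
never be used for inference.

## Reported metrics

* **AUC** — computed as the normalized Mann–Whitney statistic (ties counted
  half), identical to the trapezoidal area under `roc_points()`.
* **AUC interval** — class-stratified percentile bootstrap (default 2000
  resamples, seeded). The method is assumption-light and its ~95% coverage
  is verified by simulation in the test suite against a score model with
  analytically known AUC.
* **Operating threshold** — maximizes Youden's J = sensitivity +
  specificity − 1 over the ROC thresholds, ties broken toward the smaller
  threshold ("good values for both" made precise).
* **Sensitivity/specificity intervals** — exact Clopper–Pearson from Beta
  quantiles. At the 95% level this reproduces the printed intervals for
  the operating-point counts 23/27 → (0.66, 0.96) and 17/20 → (0.62,
  0.97), which is why the exact interval (rather than a Wald or Wilson
  approximation) is the package default.
* **Descriptive outputs** — `report()` produces a selected-feature heatmap
  (the first fold's selection, patients sorted by class), a
  probability-by-group box summary (whiskers show the data range truncated
  to at most twice the interquartile range beyond the box), and a
  probability × Marsh-grade cross-tabulation over the bins 0–0.2 … 0.8–1
  (upper bin closed).

## The synthetic cohort generator

No patient-level FAIMS data are publicly deposited, so the package ships a
generator whose defaults mirror the pilot design: 27 CD vs 20 D-IBS
patients, three replicate matrix pairs each, on a 51 × 512 grid per
polarity (a plausible instrument raster; the true export dimensions are
not documented).

Per cohort, a handful of Gaussian blobs at fixed random locations model
chemical signatures; per patient, each blob gets a latent amplitude (class
mean + patient effect). Three components separate the variance scales:

* **Discriminative blobs** (default 3): class means differ by
  `effect_size × pooled between-patient SD` — `effect_size` is a Cohen's d
  at the amplitude level. Default 2, a strong signature; 0 gives a null
  cohort.
* **Between-patient variation**: blob-amplitude SD 1 for CD and 2 for
  D-IBS (IBS is a heterogeneous diagnosis of exclusion, so its profile is
  modelled as twice as variable), **plus** a smooth patient-specific
  random field over the whole plane (per-pixel SD 1, correlation lengths
  ~3% dispersion field by ~0.4 V, matching typical chemical peak widths
  and independent of grid resolution). The field models the diffuse
  inter-individual variation — diet, metabolome — that real profiles show
  everywhere, not only at the discriminative locations. Without it the
  cohort's between-patient covariance would have rank equal to the blob
  count, an unrealistically low-dimensional structure under which
  selection-leakage artifacts are artificially suppressed.
* **Within-patient noise**: iid per-pixel replicate noise, SD 0.5. Latent
  amplitudes and the field are shared across a patient's replicates, so
  replicates of one patient are more alike than scans of different
  patients whenever patient-level SDs exceed the noise SD.

Each patient draws from an own RNG substream split off the cohort seed by
counter, so cohorts are reproducible and insensitive to generation order.

Chromatograms are sums of Gaussian peaks (SD 0.02 min) on a flat baseline
with additive noise (SD 0.05 MCps): four common urinary-volatile peaks
(5.30, 7.63, 7.95, 9.76 min), one deliberately sub-threshold peak
(~1 MCps), and — in the CD class only — a marker near 4.67 min well above
the 1.8 MCps reporting threshold. Retention times jitter by at most
0.03 min, inside the default 0.05-min binning tolerance.

What the generator does **not** emulate: real ion chemistry (charge
competition, humidity and temperature drift), instrument nonlinearity and
saturation, correlated replicate drift, missing scans, or any biological
ground truth about which VOCs distinguish these diseases. Passing tests on
synthetic cohorts therefore validate the *statistical machinery* —
calibration, leakage-freedom, recovery power — not the clinical claim.

## GC-MS screen details

`detect_peaks()` subtracts a rolling-median baseline (window 0.5 min,
chosen wide relative to peak width so genuine peaks survive), then reports
local maxima exceeding the threshold (default 1.8 MCps) that dominate a
±0.05-min neighbourhood; bounds are half-height crossings. Binning is
greedy in retention-time order: a peak joins the current bin while it is
within tolerance of the previous peak and the bin span stays within twice
the tolerance; the bin center is the span midpoint, so every member is
within tolerance of its center. The 0.05-min default merges run-to-run
jitter without merging genuinely distinct peaks a few tenths of a minute
apart. A bin is class-unique if its prevalence reaches 90% in one class
(near-universal presence) with *strict* absence in the other; intensity
units (MCps) are treated as an opaque detector unit throughout.

## Numerical and design choices

* Daubechies filters of orders 1–10 are embedded as standard published
  constants; order 4 is the default compromise between support length and
  smoothness. Tests verify unit norm, even-shift orthogonality, gain
  √2 and vanishing moments of every order used.
* Variance uses the unbiased (n − 1) estimator; quantile cutoffs use the
  type-7 quantile.
* All tie-breaks (feature ranking, Youden threshold) are deterministic
  and documented; every stochastic step (internal folds, forests,
  bootstraps, generators) is seed-controlled.
* Probability bins for the cross-tabulation are left-closed with a closed
  upper bin, so 1.0 lands in 0.8–1.
* Degenerate inputs fail loudly: single-class training folds, single-row
  variance estimation, empty samples, dimension mismatches and malformed
  files all raise errors naming the offending unit.

## Problem sizes used by the packaged checks

The acceptance checks run the full pipeline on one default-grid cohort
(51 × 512, 47 patients) and use a reduced 16 × 64 grid for replicated
simulations: 100 null cohorts (nested and leaky variants) for calibration,
10 planted-signal cohorts for recovery, and 10-seed ladders for
monotonicity. These sizes were chosen so the whole suite re-runs on a
single CPU in well under half an hour while keeping Monte-Carlo error
small relative to the tested margins.

## Known limitations

* The real study's data are not deposited, so the published
  discrimination figures cannot be reproduced here; the synthetic cohort
  validates machinery, not biology.
* Pooled LOO scores retain a small residual pessimism even with balanced
  weights (null means land slightly below 0.5); the calibration band in
  the acceptance checks reflects this.
* The SVM margin-to-probability map is monotone but uncalibrated;
  threshold-based metrics for the SVM should be read accordingly.
* Recovery power at the reduced grid sits near its acceptance margin
  (long-run median AUC ≈ 0.86 at effect size 2), so individual small-seed
  batches fluctuate.
* Mass-spectral identification (library matching of the 4.67-min marker)
  is out of scope; the screen stops at retention-time evidence.
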