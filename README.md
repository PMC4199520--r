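# faimsdx

Discriminating disease classes from urinary volatile organic compound
(VOC) profiles measured by field asymmetric ion mobility spectrometry
(FAIMS), with a companion GC-MS chromatogram screen for class-unique
peaks.

A FAIMS scan of urine headspace is an ion-current matrix over
(dispersion field %, compensation voltage V), one matrix per ion
polarity, with replicate scans per patient. At pilot scale — here 27
coeliac-disease (CD) patients vs 20 diarrhoea-predominant IBS (D-IBS)
controls — the feature space (~10⁴–10⁵ pixels) dwarfs the cohort, so the
package implements the standard guard-railed workflow:

1. average replicates per patient and flatten both polarity matrices;
2. compress with a 1-D Daubechies wavelet transform (db4, periodized
   orthonormal filter bank, zero-padded to a power of two);
3. drop coefficients with low variance across the **training** patients
   (default: keep the top 5% by variance);
4. rank the survivors by two-sided Wilcoxon rank-sum p-value and keep the
   top k (default 30);
5. classify with elastic-net sparse logistic regression (α = 0.5, penalty
   tuned by internal 5-fold CV), a random forest, or a linear SVM;
6. evaluate by leave-one-out cross-validation (LOO-CV) in which steps
   3–5 are refitted inside every fold — the held-out patient never
   touches feature selection or model fitting.

Performance is summarized as AUC = P(random case outranks random
control), with a class-stratified bootstrap percentile interval; the
operating threshold maximizes Youden's J = sensitivity + specificity − 1;
sensitivity and specificity get exact Clopper–Pearson intervals
(lower = qbeta(α/2, s, n−s+1), upper = qbeta(1−α/2, s+1, n−s)).

Because no patient-level data are deposited for this design, the package
ships a synthetic cohort generator with a planted, localized class signal
(Gaussian blobs in the (DF, CV) plane whose amplitudes shift between
classes by a chosen Cohen's d) plus realistic nuisance structure
(patient-specific smooth random fields, replicate noise, larger
between-patient variance in the IBS class). Every stage of the pipeline
is validated end-to-end against it.

The GC-MS screen detects chromatogram peaks above 1.8 MCps after
rolling-median baseline subtraction, bins them across samples by
retention time (±0.05 min), and flags bins present in ≥90% of one class
and absent in the other.

## Worked example

```r
library(faimsdx)

# a synthetic study-shaped cohort: 27 CD vs 20 D-IBS, 3 replicates each,
# 51 x 512 grid per polarity, planted effect size 2
cohort <- generate_cohort(synthetic_config(seed = 11))

preds  <- run_loo_cv(cohort, pipeline_config(seed = 11))
evaluate_predictions(preds, seed = 11)
#> AUC         0.94 (0.83-1.00)
#> Sensitivity 1.00 (0.87-1.00) at threshold 0.332
#> Specificity 0.85 (0.62-0.97)
#> 27 cases vs 20 controls
```

Each patient's `prob_cd` is produced by a model that never saw that
patient. The AUC of 0.94 says a random coeliac patient outranks a random
control 94% of the time; the bracketed intervals are the stratified
bootstrap (AUC) and exact binomial (sensitivity/specificity) 95% bounds.
At the Youden-optimal threshold 0.332 all 27 cases and 17 of 20 controls
are classified correctly.

The GC-MS screen on the matching synthetic chromatograms:

```r
chroms <- generate_chromatograms(n_cd = 27, n_ibs = 20, seed = 11)
res <- screen_chromatograms(c(chroms$CD, chroms$`D-IBS`))
res$unique_bins[, c("center", "prev_cd", "prev_ibs", "unique_class")]
#>   center prev_cd prev_ibs unique_class
#> 1  4.675       1        0           CD
```

— exactly one class-unique bin, at the planted 4.67-min marker, present
in every coeliac chromatogram and no control.

A thin command-line front end (`inst/scripts/faimsdx.R`) exposes
`simulate`, `run` and `gcms-screen` subcommands over the same functions.

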