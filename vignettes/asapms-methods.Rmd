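---
title: "Methods: from raw ASAP-MS scan streams to consensus biomarker peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw ASAP-MS scan streams to consensus biomarker peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`asapms` implements an end-to-end analysis for linking ambient-ionisation
mass-spectrometry "molecular fingerprints" of blood plasma to binary clinical
outcomes. This vignette is the package's own account of the methods: the
processing model and its assumptions, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical conventions adopted where more than one convention is defensible.

## 1. The measurement model

An atmospheric solids analysis probe (ASAP) instrument completes a scan
roughly every 0.9 s throughout an acquisition. The raw file is therefore a
time-ordered stream of scans: some recorded while no probe was present
("background"), and some recorded during the five successive insertions of a
sample-loaded probe. Each insertion produces a sharp rise in the total ion
count (TIC), because the sample dramatically increases the number of ions
reaching the detector.

The preprocessing chain (`process_acquisition()`) converts one stream into one
spectrum in five steps:

1. **Segmentation** (`segment_acquisition()`). The background TIC level is
   estimated as the median TIC of the leading scans (the acquisition must open
   in background; a stream whose first scan is already high is rejected). A
   scan is classified "high" when its TIC is at least `rise_factor` (default
   5) times that level, and a sample window is any maximal run of at least
   `min_window_scans` (default 5) consecutive high scans. The run-length
   minimum rejects transient spikes; both parameters are exposed because the
   rise is a qualitative instrument phenomenon, not a calibrated quantity.
2. **Unit-mass binning** (`bin_to_unit_mass()`). Peaks are summed into integer
   m/z bins under the round-half-up convention: bin $k$ covers
   $[k - 0.5,\, k + 0.5)$, so a peak at exactly $m/z = 100.5$ falls into bin
   101. Binning removes the need for fine spectral alignment at the
   resolution of compact ASAP instruments. Peaks outside the configured bin
   range are dropped and tallied, so total intensity is conserved up to the
   reported dropped mass. The default range is m/z 11–1000 inclusive — 990
   unit-mass bins covering the small-molecule region these instruments
   measure.
3. **Window averaging** (`summarize_window()`). Per-bin mean and standard
   deviation across the scans of each window, computed after binning so all
   scans share one axis. The *population* SD convention (N divisor) is used
   and documented; with ~30 scans per window the distinction from the sample
   SD is immaterial, but a fixed convention makes replicate SDs reproducible.
4. **Background subtraction** (`subtract_background()`). The background-window
   mean spectrum is subtracted from each sample-window mean. Negative
   differences are clipped to zero — the downstream $\chi^2$ feature ranking
   requires nonnegative features — and the clipped mass is reported so a
   noisy background cannot silently distort spectra.
5. **Normalisation and replicate averaging** (`normalize_unit_area()`,
   `average_replicates()`). Each corrected spectrum is divided by its total
   intensity (unit area under the spectrum), then the five replicates are
   averaged. The mean of unit-area vectors already has unit area, so the
   average is deliberately *not* re-normalised; fixing this order makes the
   pipeline unambiguous. Area normalisation is used because, for data of this
   kind, the choice among common normalisation schemes has little effect on
   downstream classification.

At zero noise the composition is exactly invertible: simulating an
acquisition from a known spectrum and processing it back recovers the
unit-area spectrum to within floating-point error. That round trip, together
with 100%-recovery of planted windows across 100 simulated acquisitions, is
asserted by the test suite.

## 2. Cohort construction

Clinical variables are turned into binary tasks by published thresholds:
microvascular obstruction (MVO) zero versus non-zero, index of
microcirculatory resistance (IMR) at 40, ischemic time at 6 h, peak troponin
at 50, creatinine at 75, thrombus score grades 1–3 versus 4–5, and the
already-binary mortality and heart-failure-diagnosis (HFD) outcomes. Two
conventions required a decision:

* **Threshold boundaries.** The published rules use strict inequalities on
  both sides (e.g. IMR < 40 versus IMR > 40), leaving the boundary value
  unassigned. Values exactly at a threshold are assigned to the 'Low' class
  and counted in a boundary report, so the choice is auditable. For MVO the
  boundary *is* the rule (MVO = 0 defines the 'Low' class), so no boundary is
  reported there.
* **Thrombus score 0.** The grade ranges 1–3 and 4–5 never mention grade 0;
  such patients are treated as missing for this task and counted.

Balanced datasets (`balanced_subset()`) keep every minority-class patient and
undersample the majority class to the same count, so a classifier cannot
score well by guessing the prevalent class. Extreme-patient datasets
(`extreme_subset()`) take the 20 or 30 lowest and highest values of a
continuous variable (40 or 60 spectra), sharpening class separation for pilot
analyses; ties at either cut break by stable sample-ID order. Extreme
variants are undefined for the categorical outcomes (mortality, HFD) and the
grid refuses them. Missing labels are excluded before balancing; no
imputation is performed anywhere.

Demographic augmentation appends age, weight, height, BMI, body surface
area, smoking status, hypertension, diabetes, and previous cardiological
history as extra columns. Continuous parameters are rescaled from their
observed range onto $[0, m]$ and binaries mapped to $\{0, m\}$, where $m$ is
the median positive spectral intensity — preventing demographic columns from
dominating distance-based learners. "Rescaled to the median intensity" is
ambiguous between per-spectrum and global medians; the package uses one
global $m$, and during evaluation both $m$ and the ranges are refit on each
partition's training rows only, so augmentation cannot leak test-set
information. Patient sex is never included (warned and skipped if requested),
and patients missing any listed parameter are dropped and counted.

## 3. Feature reduction

Three per-partition methods, always fit on training rows only:

* **Point-biserial correlation** (`pearson_select()`): the Pearson
  correlation between each bin's intensity and the 0/1 label, tested
  two-sided; bins with $P < 0.05$ are kept. No multiple-testing correction is
  applied by default — the method is a plain per-peak significance gate, and
  the permissiveness is intentional because the repeated-partition consensus
  (below) supplies the stability control; an optional Benjamini–Hochberg gate
  is available (`fdr = TRUE`). A Shapiro–Wilk normality fraction can be
  reported as a diagnostic; it justifies the parametric test descriptively
  and is never enforced, and it is off by default because ~990 Shapiro tests
  per call are wasteful inside a 200-partition loop.
* **Overlap integrals** (`overlap_select()`): for each bin, the two class
  intensity distributions are histogrammed on shared equal-width cells
  spanning the pooled min–max, each normalised to unit sum, and the overlap
  is the summed cellwise minimum. An overlap near 1 means the classes are
  indistinguishable at that bin; the 40 smallest-overlap bins are kept. The
  cell rule — $\max(5, \lceil\sqrt{n_{\text{pooled}}}\rceil)$ cells — is
  symmetric in the groups, scale-adaptive, and simple enough to verify by
  hand; the integral is symmetric, lies in $[0,1]$, and is invariant under a
  common affine rescaling of both groups and the edges.
* **$\chi^2$ ranking** (`chi2_select()`): the frequency-style statistic on
  nonnegative intensities — class-wise intensity sums compared with the
  totals split by class proportion — ranks bins by "importance"; the top 40
  are kept. This is the standard $\chi^2$ feature-ranking convention for
  nonnegative features (continuous intensities treated as frequencies) rather
  than a quantile-binned contingency test, which would discard the intensity
  scale.

Ties everywhere break by ascending bin label, making selections fully
deterministic. A bin becomes a **consensus feature**
(`consensus_features()`) when, for each of the three methods separately, it
is selected in *strictly more than* 75% of that method's training partitions.
Counting is per data partition; whether stability should instead be counted
per model-training run is ambiguous, and the per-partition reading was chosen
because selection is independent of the classifier.

## 4. Evaluation

`run_evaluation()` repeats, 200 times by default: draw a stratified 80:20
partition (per class, $\lfloor 0.8\, n_c \rfloor$ to training — 20 of 25),
select features on the training rows, standardise both splits by
training-row statistics, fit one of five classifiers, predict the test rows,
and score. The classifiers — k-nearest neighbours ($k=5$, Euclidean), an RBF
support vector machine (cost 1), linear discriminant analysis, Gaussian naive
Bayes, and a 100-tree random forest — are invoked through a registry of
fit/predict closures with pinned, overridable hyperparameters; only the model
families are canonical, so library defaults are pinned in one place rather
than hidden. Per-partition seeds derive from the base seed by a counter, so
any single partition is replayable.

Scores are percentage accuracy, $100\,(TP+TN)/N$, and Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ with marginal-product expected agreement,
reported as mean ± SD over partitions. Partitions with undefined $\kappa$
(both marginals degenerate) or an empty feature selection are excluded from
the means with explicit counts, never imputed. Mean $\kappa$ maps to
agreement bands (below 0.2 none, 0.2–0.4 weak, 0.4–0.6 fair, 0.6–0.8
moderate, 0.8–0.9 strong, above 0.9 very strong; shared boundaries go to the
lower band), and small-sample significance requires $\kappa \ge 0.6$ for
datasets of at most 50 samples and $\kappa \ge 0.5$ up to 60.

**Null calibration.** `permute_labels = TRUE` permutes the labels freshly in
every repetition before partitioning. A single fixed permutation is *not*
used: its chance overlap with the true classes (hypergeometric, SD about 1.8
patients at 25 per class) would propagate through all 200 partitions as a
systematic accuracy offset of several percent; re-permuting per repetition
averages that residual out and estimates the pipeline's true chance level.

## 5. The synthetic cohort generator

The generator exists so that every downstream stage is exercisable and
testable without patient data; it is first-class, tested code.

* **Clinical tables** (`generate_clinical_table()`): continuous variables are
  log-normal (right-skewed, as registry data are), MVO is zero-inflated
  (default 50% exact zeros, matching the "most patients have zero or near-zero
  MVO" structure that motivates its zero/non-zero task), binary variables use
  prevalences in the range reported for STEMI registries (e.g. ~9% mortality,
  ~11% HFD, ~82% male), and every variable is masked missing independently at
  a configurable fraction (defaults ~6% for most variables, ~30% for
  smoking history, ~20% for HFD). The medians of the continuous variables sit
  near their task thresholds so both classes are populated.
* **Spectra** (`generate_spectrum_matrix()`): replicate spectra are drawn
  around a smooth, strictly positive baseline profile with multiplicative
  log-normal noise at a configurable replicate coefficient of variance
  (default scenarios use 0.3, inside the sub-40% reproducibility typical of
  plasma ASAP measurements), then unit-area normalised and averaged exactly
  as the preprocessing module would. Class-1 patients have the mean intensity
  at each planted bin multiplied by the effect size *before* normalisation.
* **Inter-patient variance** is a free parameter (`biological_cv`, default
  0): no replicate-reproducibility statement constrains it, and a zero
  default keeps the generator's documented zero-noise contracts exact (at
  `noise_cv = 0` the class-1 pre-normalisation mean is *exactly*
  `effect_size` times the class-0 mean). Raising it makes classification
  realistically harder and is the first knob to turn when stress-testing.
* **Raw acquisitions** (`simulate_raw_acquisition()`): a scan stream at the
  configured cadence — one leading background window, then five sample
  windows separated by background gaps, with the sample TIC about 10× the
  flat instrument background — carrying its ground-truth window boundaries so
  segmentation is testable without manual annotation.

What the generator does **not** emulate: ion chemistry, adducts and
fragments, instrument drift, batch effects, and correlated biological
structure across bins. Passing tests therefore demonstrate that the pipeline
is *correct* (it recovers what was planted, under the stated noise), not that
any particular clinical signal is detectable in real plasma.

## 6. Problem sizes and reproducibility

The packaged study scenario uses 25 patients per class, six planted bins at a
three-fold effect, 30% replicate CV, and 200 partitions — the scale at which
the consensus criterion and the LDA evaluation are asserted in the test suite
and recomputed by `scripts/acceptance.R`. Unit tests use smaller cohorts and
narrower bin ranges chosen to exercise each contract at the least size that
makes the property non-trivial. All randomness flows through explicit seeds;
every generator and the whole evaluation loop are pure functions of their
inputs and seed.

## 7. Known limitations

* The $\kappa$ significance rule is a fixed small-sample threshold pair, not
  an exact test; it mirrors the reporting convention for pilot cohorts of
  this size.
* Box-and-whisker summaries (`export_group_distributions()`) use R's default
  linear-interpolation quartiles (type 7); whiskers extend to the farthest
  point within 1.5 × IQR of the box, and significance per bin is an
  independent two-sample t-test with equal variances.
* The grid's resumability is keyed by cell identity (task, variant, method,
  model, demographics flag) in the output directory; changing generator
  parameters without clearing the cache will mix results.
* mzML reading requires the optional `mzR` dependency; the long-format scan
  CSV needs none.
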