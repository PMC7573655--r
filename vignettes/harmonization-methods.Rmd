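---
title: "Harmonizing multi-scanner brain morphometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-scanner brain morphometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roiharmony)
```

## The problem

Volumes of brain structures segmented from T1-weighted MRI depend not only on
the subject but on the scanner and acquisition protocol that produced the
image: field strength, gradient non-linearity, contrast-to-noise, motion and
resolution all distort the measured volumes. Pooling regions-of-interest (ROI)
tables across sites therefore mixes biology with scanner bias. ComBat-style
empirical-Bayes harmonization removes that bias well, but it needs a
statistically representative sample *per scanner* — useless for the clinical
case of a single image from a scanner never seen before. roiharmony
implements both halves of the standard answer: (1) ComBat harmonization with
covariate control for the multi-site training corpus, and (2) a regression
model that learns how per-image quality metrics (IQMs — scalar measures such
as contrast-to-noise ratio or FWHM computable from one image in isolation)
map to the per-ROI corrections ComBat prescribes, so that new single images
can be harmonized from their own intrinsic characteristics.

All harmonization operates on *relative volumes* `v = ROI volume / TIV`
(total intracranial volume), which removes head-size variation and is
dimensionless.

## Quality control

The exclusion pipeline mirrors standard multi-site practice, in order:

1. **Age window** 18–70 years, boundaries inclusive (subjects strictly
   younger/older are excluded).
2. **Quality probabilities**: any available "probably unusable" probability
   (image-level, segmentation-level) strictly greater than 0.5 excludes the
   subject. Values outside [0, 1] are an error.
3. **Missing data**: rows with any missing ROI or IQM value are excluded and
   counted; imputation is deliberately not offered.
4. **Iterative per-scanner outlier removal**: within each scanner, a subject
   is flagged when its relative volume lies more than 2.5 sample standard
   deviations from the scanner mean on at least 10 ROIs (roughly 10% of a
   ~100-ROI feature space; a fractional mode is available). All flagged
   subjects are removed at once and the moments recomputed until a fixed
   point. Batchwise removal makes the result deterministic and independent of
   row order; per-scanner operation guarantees that between-scanner offsets
   can never masquerade as outliers.
5. **Minimum scanner size**: scanners with fewer than 5 retained subjects are
   dropped entirely (the empirical-Bayes machinery is unreliable below that).

The report object partitions the input count exactly; every excluded subject
carries exactly one primary reason.

## ComBat: the location/scale model

For feature (ROI) $g$, subject $i$ of batch $b$:

$$y_{big} = \alpha_g + X_i \beta_g + \gamma_{bg} + \delta_{bg}\,\varepsilon_{big}$$

with $\gamma$ an additive and $\delta$ a multiplicative batch effect. Fitting
follows the standard parametric empirical-Bayes recipe: estimate
$\hat\alpha_g$ (batch-size-weighted grand mean), $\hat\beta_g$, and the pooled
variance; standardize; estimate per-batch $\hat\gamma_{bg}$,
$\hat\delta^2_{bg}$; fit a normal prior to the $\hat\gamma$ and an
inverse-gamma prior to the $\hat\delta^2$ across features by method of
moments; and iterate the conditional posterior updates of
$(\gamma^*, \delta^*)$ to a fixed point (relative tolerance $10^{-6}$,
capped at 1000 iterations). The adjusted value is

$$y^* = \sqrt{\tfrac{\sigma^2_g}{\delta^{*2}_{bg}}}\,(z_{big} - \gamma^*_{bg})
        + \alpha_g + X_i\beta_g .$$

Numerical conventions, chosen once and tested:

* Per-batch variances and the pooled variance both use the
  maximum-likelihood denominator ($n$, not $n-1$). This makes the one-batch
  limit *exactly* the identity ($\gamma^* = 0$, $\delta^* = 1$), which the
  $n-1$ convention violates by a factor $n/(n-1)$.
* Empirical-Bayes shrinkage needs at least two batches and two features;
  degenerate hyperpriors (zero between-feature variance) disable shrinkage
  for that batch with a warning rather than producing NaNs.
* Batches with a single subject and features with zero pooled variance are
  errors naming the offender.
* Transforming a row whose batch was never seen is an error that points the
  user at the learner — predicting such corrections is precisely what the
  quality-metric model is for.

## The stepwise scheme and what each step may absorb

Multi-site cohorts are typically badly imbalanced in sex and age, so
`stepwise_harmonize()` applies three ComBat instances in sequence — sex as
batch, then integer-rounded age as batch (half away from zero; categories
with fewer than 5 subjects merged into the nearest category, ties to the
lower), then scanner as batch — recording per-step and cumulative
corrections (`harmonized − raw`, telescoping exactly).

One default here deserves its own paragraph. If the sex and age steps are run
with no other covariate in the model, each age category's effect is the mean
of whichever scanners happen to populate that category. When scanner effects
and scanner demographics are correlated — which at a dozen scanners happens
by chance alone — the age step then absorbs part of the *scanner* bias, and
the per-step corrections decompose wrongly even though their sum still fits
the training data. That is invisible in-sample but poisonous for the learner,
which must transfer the decomposition to new scanners with new demographics.
We measured exactly this failure on simulated worlds. The default therefore
preserves scanner variance during the sex and age steps (scanner indicator
columns as regression covariates), so covariate effects are identified from
within-scanner contrasts only; covariate columns aliased with the batch
(e.g. an age category present in a single scanner) are dropped with a
warning. Passing `preserve = list()` restores the unconditional removal.

## Assessing harmonization

Distinguishability is measured exactly as a reviewer would: the two-sample
Kolmogorov–Smirnov test per ROI for every unordered scanner pair, reduced per
pair to the minimum p over ROIs (the worst-harmonized region). No
multiple-comparison correction is ever applied: when screening for residual
scanner bias the costly mistake is the type II error, so per-test p-values
are reported against a 0.001 reference line. Asymptotic p-values (effective
size $n_x n_y/(n_x+n_y)$) are the default; an exact, tie-aware mode is
available and recommended below a combined n of 30. The exact mode is
verified in the test suite against an independent exhaustive-permutation
oracle.

Correction strength per ROI is summarized by the correction ratio
(median volume / median |correction|), its reciprocal as a percentage, and
for context the coefficient of variation $CV = 100\,\sigma/\mu$ (sample SD)
and quartile-based $QCV = 100\,(Q_3-Q_1)/Q_2$ with linear-interpolation
quartiles — QCV depends on the quartile convention, so it is stated.
Per-covariate contributions take, per scanner and per step, the median over
subjects of |step correction| summed over ROIs, normalized to shares summing
to one (the median-over-subjects reading; the transposed reading is
available as an argument).

## The unseen-scanner learner

The learner captures `correction_ROI = f(IQMs, age, sex, vROI)` from ComBat
output. The feature matrix contains the IQM columns, age, sex (0/1) and the
raw relative volumes of the target ROIs; a single principal-component basis
is fitted on the standardized features, retaining the smallest number of
components whose cumulative explained variance reaches 99% (standardization
because IQMs have wildly different natural scales; the retained count is
data-driven, not hard-coded). One random-forest regressor per ROI is fitted
on the shared components, targeting the cumulative correction by default
(per-step targets are selectable). Prediction needs only a single subject's
own features — no batch statistics — so one image from an unknown scanner is
a valid input; the harmonized value is `vROI + predicted correction`.

Because no random-forest package is part of the supported environment, the
package ships its own regression forest (bagged CART, variance-reduction
splits, midpoint thresholds between distinct values, deterministic tie
handling) in C++, driven by R's RNG so that a fixed seed reproduces the model
bit-for-bit. Defaults follow the common scikit-learn-style convention: 100
trees, all features considered at each split, minimum leaf 5, unlimited
depth.

Hyperparameters can be tuned by leave-one-scanner-out cross-validation: for
the split only, scanners under 30 subjects are pooled into one pseudo-scanner
and the largest scanner is randomly under-sampled to the size of the second
largest (so a mega-site cannot dominate every training fold); the grid point
minimizing mean fold MAE is chosen per ROI, ties resolved toward fewer trees,
then shallower depth. The final model is refit on all data unmerged.

Training feature ranges are stored in the model; at prediction time every
(subject, feature) pair outside the envelope is flagged and a warning raised,
but the prediction is still returned — the tool warns, it does not refuse.

An alternative layout, `method = "detrended"`, first estimates the age/sex
component of the correction by within-scanner fixed-effects regression and
lets the forest fit only the scanner-driven remainder from IQM components
plus the ROI volume. It was built while diagnosing the confounding issue
above and is kept for settings where covariate effects must extrapolate far
outside individual scanners' demographic windows; with the preserve-scanner
stepwise default, the plain PCA pipeline was at least as robust on simulated
worlds and remains the default.

## The simulator: a stated world

`simulate_cohort()` emulates the *structure* of a large multi-site
morphometry corpus so every claim is testable without any data download. Its
defaults were chosen once, on realism grounds:

* 10 scanners × 80 subjects, 20 ROIs, 10 IQMs — desk scale; the ~100-ROI /
  68-IQM scale of real pipelines is a configuration choice, not a constant.
* ROI means log-spaced over 5×10⁻⁴–3×10⁻² of TIV (the range spanned by real
  subcortical through lobar structures); natural between-subject SD 8% of
  the mean (real relative volumes show CVs around 5–15%).
* Age drawn uniformly from a per-scanner window of half-width 15 years inside
  18–70 (sites recruit different populations) and sex with per-scanner
  imbalance Uniform(0.2, 0.8) — both mirroring the gross imbalance of real
  multi-site samples.
* Age slopes per ROI ~ Normal(−0.2%, 0.1%) of the mean per year (≈ 10%
  decline across the adult range, the order reported for grey-matter
  structures); sex offsets ~ Normal(0, 1.5%) of the mean (small after TIV
  normalization).
* Scanner effects driven by a one-dimensional latent quality
  $q_s \sim U(-1, 1)$: additive $\gamma_{sg} \propto q_s$ with per-ROI
  amplitude up to ~1.5 within-scanner SD, multiplicative
  $\delta_{sg} = e^{d_g q_s}$ with $d_g \in [0.05, 0.2]$ (scale distortions
  up to ±20%) — bias comparable to, but smaller than, natural variability,
  as observed in real corpora. Both maps are smooth and monotone in $q$, so
  the IQM→correction relationship is learnable in principle.
* IQMs linear in $q_s$ with subject noise SD 0.05 (quality metrics are
  strongly scanner-associated); observation noise 10% of the natural SD.

Ground truth (latent qualities, per-scanner-by-ROI effects, true volumes) is
returned alongside, and `make_validation_split()` holds out whole scanners,
by default stratified so held-out qualities lie strictly inside the training
envelope — validating interpolation, which is all the range-check warning
promises.

What the simulator does **not** emulate: image or voxel content, MRI physics,
pathology, site-by-disease interactions, non-monotone or multi-modal scanner
artefacts (e.g. double-peaked volume distributions, which location/scale
corrections cannot fix), and IQM sets whose information content differs
qualitatively from a 1-D quality factor. A green test here establishes that
the machinery composes correctly under the stated world, not that real data
of any particular site will harmonize.

## Known limitations

* **Few scanners bound the learner.** With 9 training scanners the forest
  sees 9 support points of the quality axis; corrections for held-out
  scanners near the edge of the envelope, where multiplicative effects are
  largest, interpolate worst. On surveyed simulated worlds the end-to-end
  unseen-scanner check (90% of ROIs at K–S p ≥ 0.001 against the
  ComBat-harmonized reference) passes in 9 of 10 draws; the failing draw
  holds out the most extreme-quality scanner whose demographic window also
  mismatches its only quality-twin. Real corpora with dozens of training
  scanners do not sit in this regime.
* **Location/scale only.** ComBat cannot correct distribution-shape
  artefacts; neither can a learner trained on its corrections.
* **Empirical-Bayes idempotence is approximate.** Re-harmonizing harmonized
  data is an exact no-op only with shrinkage off; with shrinkage the residual
  is of the order of the shrinkage itself. The test suite pins the exact
  property in the no-shrinkage mode.
* **Healthy-cohort assumption.** The QC outlier rule assumes outliers are
  artefacts, which is appropriate for healthy controls only.
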