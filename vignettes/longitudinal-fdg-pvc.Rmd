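---
title: "Longitudinal FDG-PET quantification with partial volume correction: models and design"
author: "longpet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal FDG-PET quantification with partial volume correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longpet)
```

## What the package models

`longpet` implements the quantitative core of a longitudinal brain FDG-PET
group study: two groups of subjects (ApoE &epsilon;4 carriers and
non-carriers with mild cognitive impairment) are scanned repeatedly over
seven years, and the question is whether regional glucose uptake declines
faster in carriers. The pipeline has five stages:

1. **Partial volume correction (PVC).** PET resolution (about 8 mm FWHM) is
   coarse relative to structures such as the amygdala or caudate, so signal
   spills between regions and into background. The package corrects uptake
   images with the iterative *reblurred Van Cittert* deconvolution
   \deqn{f_{k+1} = f_k + \alpha\, h \otimes (g - h \otimes f_k),}
   where \eqn{g} is the observed image, \eqn{h} an isotropic Gaussian point
   spread function, and \eqn{\alpha} the step length.
2. **SUVR quantification.** Images are scaled by the mean uptake of a
   reference region (cerebellum) to give standardised uptake value ratios,
   and summarised as ROI means over a label atlas, including a voxel-weighted
   *global cortex* union of nine cortical regions.
3. **Region-level inference.** For each region, a linear mixed-effects model
   `suvr ~ sex + education_years + baseline_age + month * carrier +
   (1 | subject_id)` is fitted by REML; the carrier-by-time coefficient (SUVR
   per month) is the quantity of interest, tested by a Wald z statistic.
4. **Voxelwise inference.** A paired t test compares each subject's follow-up
   image with baseline; suprathreshold voxels (one-tailed cluster-forming
   p&nbsp;&lt;&nbsp;0.001 for decline, 18-neighbour connectivity) are grouped
   into clusters, and cluster-level family-wise error is controlled by
   sign-flip permutation of the paired differences.
5. **Cohort statistics.** Conversion to dementia is compared by a Pearson
   chi-square without continuity correction (one-tailed where directional),
   and time to conversion by Kaplan-Meier curves and a Fleming-Harrington
   weighted log-rank test.

Because the study's images are access-restricted, all stages are exercised on
a fully synthetic phantom cohort whose statistical structure matches the
study design; nothing in the analysis code depends on the data being
synthetic.

## The phantom generator and what it emulates

`simulateCohort()` draws 24 carriers and 24 non-carriers (configurable)
scanned at months 0, 6, 12, 18, 24, 36, 48, 60, 72, 84. Per region the true
uptake follows

> truth = intercept(group) + subject deviation + slope(group) x month + visit deviation,

with the cerebellum pinned at exactly 1.0 so true uptake and true SUVR
coincide. Default parameters:

* **Intercepts and slopes.** Eight regions (superior frontal,
  lateral/medial temporal, parietal, posterior cingulate, amygdala, caudate,
  thalamus) carry a carrier-vs-non-carrier contrast parameterised as mean
  percent change per follow-up interval (e.g. parietal: &minus;1.5%/interval
  in carriers against &minus;0.31% in non-carriers, with group-specific
  baseline SUVRs). `slopeForPercentChange()` inverts the percent-change
  summary exactly for the scan schedule, so the generator's slopes are not a
  small-slope approximation. All other regions share a mild
  &minus;0.2%/interval decline; the interaction is null there.
* **Subject deviation** (SD 0.05 SUVR) is a per-subject-per-region random
  intercept, matching the fitted random-effects structure.
* **Visit deviation** (SD 0.015 SUVR) models biological and measurement
  test-retest variability at the ROI scale, at the low end of reported FDG
  SUVR test-retest values; it is the main driver of inferential uncertainty
  in ROI models because voxel noise averages out over a region.
* **Voxel noise** (SD 0.02 SUVR) is additive i.i.d. Gaussian on the blurred
  image.
* **Conversion hazards** are exponential (0.00929/month carriers,
  0.00560/month non-carriers), chosen so the expected conversion fractions by
  84 months match the observed 13/24 and 9/24; censoring is administrative
  at the last scan.
* **Atrophy** (off by default) erodes each region's boundary voxels at a
  fractional rate per month, emulating volume loss that makes PVC matter in
  longitudinal studies.

What the phantom does *not* emulate: anatomically realistic geometry (regions
are seeded Voronoi cells in an ellipsoid), scanner-specific noise texture,
motion or registration error, missed visits, and spatially correlated
biological change. Passing tests therefore demonstrate correctness of the
algorithms and calibration of the inference under the stated model, not
robustness to those real-data complications.

## Numerical choices

* **Convolution** is separable with half-sample-symmetric (mirror)
  boundaries. This makes the discrete blur operator doubly stochastic for a
  unit-sum kernel, so the global image sum is conserved exactly — the flux
  property that gives the Van Cittert iteration its clean geometric error
  decay (ratio |1&nbsp;&minus;&nbsp;&alpha;| per step, 0.5 at the default
  &alpha; = 1.5). Kernels are truncated at 4&sigma; and renormalised.
* **Stopping rule.** "Relative percent change" is implemented as the global
  L1 ratio `100 * sum|f_new - f_old| / sum|f_old|`, robust to isolated
  voxels and symmetric with the flux accounting; iteration stops below 1%
  (default) or at 30 iterations. A divergence guard aborts if the change
  grows beyond its initial value for three consecutive iterations.
* **No non-negativity clipping.** Linear deconvolution can produce small
  negative voxels; clipping would break the linear flux property, so
  negatives are counted and reported instead.
* **t-to-z conversion** uses the probability-matched quantile
  `qnorm(pt(t, df))` computed on the log scale for tail accuracy, and peak
  effect sizes use the paired convention d = z/&radic;n.
* **Permutation p-values** use the add-one estimator
  `(1 + #exceedances) / (1 + B)` for sampled sign flips (identity excluded),
  switching to exact enumeration of all 2^n patterns whenever the request
  reaches 2^n.
* **Degenerate inputs.** Voxels with zero paired-difference variance are
  masked out and counted; empty atlas regions are dropped with a warning; a
  non-positive reference-region mean is an error.

## Design decisions that were genuinely open

* **Carrier main effect.** The model specification names the
  carrier-by-time interaction but is silent on the carrier main effect; it
  is retained for model hierarchy, so the interaction is interpreted against
  group-specific baselines.
* **Time coding.** "Follow-up period" is coded as the continuous per-scan
  month from baseline (the interaction's time axis), not each subject's
  total follow-up duration.
* **Random effects.** Intercept-only by default, matching the generator;
  a per-subject random slope is available (`randomSlope = TRUE`) for data
  with heterogeneous trajectories.
* **Inference on the interaction** is a Wald z on estimate/SE from the REML
  fit. With 48 subjects and ~480 observations the normal approximation is
  adequate; the null-calibration test (below) verifies its type-I error
  empirically. No multiplicity correction is applied across regions,
  mirroring per-region reporting at p &lt; 0.05; this is a documented
  limitation, not a recommendation.
* **Fleming-Harrington weights.** The weight family for the conversion test
  is not pinned down by the study description; the default is (p = 1, q = 0),
  early-difference weighting, configurable. With p = q = 0 the test reduces
  exactly to the standard log-rank, which is cross-checked against
  `survival::survdiff`.
* **FWER mechanism.** Cluster-level correction uses sign-flip permutation
  rather than Gaussian random-field theory. Permutation is exactly valid at
  desk scale and assumption-light; numerical cluster p-values are therefore
  not expected to match random-field-theory software, though the
  cluster-forming convention (one-tailed p &lt; 0.001, 18-connectivity) is
  the same.

## Calibration experiments and problem sizes

The test suite runs every stage at sizes chosen for a desk machine:

* PVC properties run on a 40x48x40 grid at 1.5 mm (a scaled-down
  template-like volume). The 1% stopping rule converges in about 9
  iterations on brain-like phantoms.
* **Contrast recovery** uses the field's standard sphere-phantom design:
  six spheres of 130-460 voxels at contrasts from 5% to 30% (hot and cold)
  in a uniform warm background; PVC must strictly reduce every sphere's
  ROI-mean error. On the full cohort atlas this property intentionally is
  *not* asserted: for a cold region embedded in a mixed bright surround the
  blurred ROI mean can sit close to truth through cancellation of spill-in
  and spill-out, and partial deconvolution then transiently increases the
  ROI error even though the image is closer to truth voxelwise. This is a
  known property of ROI-mean summaries under deconvolution, and is why
  sphere phantoms are the standard validation target.
* **Mixed-model calibration** refits 200 replicate null cohorts (equal
  slopes, visit noise on) and checks the 5% rejection rate against the
  binomial 95% band; exact parameter recovery is checked on a zero-noise
  cohort to 1e-6.
* **FWER calibration** uses 200 null datasets of 12 paired 16^3 images with
  500 sign-flip permutations each. This experiment forms clusters at
  p &lt; 0.01 rather than the pipeline's 0.001: at desk-scale grids the
  0.001 threshold leaves the null maximum-extent distribution so discrete
  that corrected p &lt; 0.05 is essentially unattainable (the empirical rate
  degenerates to 0 — conservative, not miscalibrated), whereas at 0.01 the
  5% level is attainable and the band check is informative.
* **PVC sensitivity** (the qualitative claim that small regions reach
  significance only after correction) is demonstrated with atrophy enabled
  on 12-subject-per-group cohorts on a 32x36x32 grid with visit SD 0.04
  (test-retest-scale variability); across seeded replicates the PVC run
  flags a superset of the non-PVC run's regions, with the amygdala as the
  typical PVC-only detection.

## Known limitations

* ROI means over a fixed atlas cannot undo atrophy bias: eroded voxels stay
  inside the ROI mask, so even perfect deconvolution leaves a volume-loss
  trend. PVC reduces, but does not remove, this effect.
* The Van Cittert iteration recovers structure down to roughly the PSF
  scale; contrast in structures much smaller than the FWHM (here, below
  about 100 voxels at 8 mm / 1.5 mm) is only partially restored, and cold
  small structures embedded in bright surroundings may see little ROI-mean
  benefit (see above).
* Wald z inference is mildly anti-conservative at small cohort sizes; the
  calibration test bounds this at the default design but users fitting much
  smaller cohorts should prefer the random-slope model and treat borderline
  p-values cautiously.
* The phantom's missingness model is optimistic (every subject attends every
  visit); mixed models tolerate unbalanced schedules, but no test exercises
  informative dropout.
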