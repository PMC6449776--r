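# longpet

Longitudinal brain FDG-PET quantification with partial volume correction,
for imaging statisticians studying group differences in metabolic decline —
the prototypical case being ApoE ε4 carriers versus non-carriers with mild
cognitive impairment followed over seven years.

## What it computes

* **Partial volume correction** by the iterative reblurred Van Cittert
  deconvolution
  f<sub>k+1</sub> = f<sub>k</sub> + α·h⊗(g − h⊗f<sub>k</sub>),
  with an isotropic Gaussian PSF h (default 8 mm FWHM), step length α = 1.5,
  and a 1% relative-change stopping rule.
* **SUVR imaging and ROI summaries**: voxelwise division by the
  cerebellum mean, ROI means over a label atlas, a voxel-weighted global
  cortex composite, and Table-style mean percent change per follow-up
  interval.
* **Per-region longitudinal inference**: the linear mixed-effects model
  `suvr ~ sex + education_years + baseline_age + month * carrier +
  (1 | subject_id)` (REML, `lme4`), reporting the carrier-by-time
  interaction in SUVR/month with a Wald z test.
* **Voxelwise paired-t analysis** of follow-up versus baseline with
  probability-matched z and Cohen's d (= z/√n) maps, 18-connectivity
  clusters at one-tailed p < 0.001, and cluster-level FWER by sign-flip
  permutation (exact enumeration when feasible).
* **Cohort statistics**: Pearson chi-square on conversion counts (one- or
  two-tailed, no continuity correction), Kaplan–Meier conversion-free
  survival, and a Fleming–Harrington weighted log-rank test.
* **A synthetic phantom cohort** (atlas, subject records, ground-truth
  trajectories, rendered blurred noisy visit images) with the same
  statistical structure, so the whole pipeline runs and calibrates without
  restricted data.

## Worked example

```r
library(longpet)

atlas   <- makeAtlas(seed = 1)          # seeded 25-region parcellation
cohort  <- simulateCohort(seed = 1)     # 24 carriers + 24 non-carriers
suvr    <- simulateSuvrTable(cohort)    # long (subject, month, region) table
subjects <- subjectTable(cohort)

fitRoiLmm(suvr, "parietal", subjects)
#>     region  estimate        se      z          p nObs converged
#> 1 parietal -0.001198 5.134e-05 -23.33 2.165e-120  480      TRUE

meanPercentChange(suvr, "parietal", subjects, carrier = TRUE)   # -1.46
meanPercentChange(suvr, "parietal", subjects, carrier = FALSE)  # -0.31

chisq2x2(13, 11, 9, 15, tail = "one")$p
#> [1] 0.1232829
```

The interaction estimate −0.0012 SUVR/month is the extra monthly parietal
SUVR loss in carriers relative to non-carriers — the generator injected a
−1.5% vs −0.31% per-interval contrast, and the mean-percent-change summary
returns it to within visit noise. The chi-square line is the one-tailed test
on the conversion counts 13/24 vs 9/24 (p = 0.123).

Image-space stages work the same way on rendered visits:

```r
img  <- renderVisitImage(cohort, "C01", 0, atlas, psfFwhmMm = 8, seed = 1)
pvc  <- vanCittertPVC(img, fwhmMm = 8)          # $corrected, $changeHistory
suvr0 <- computeSuvr(pvc$corrected, atlas)      # $image, $regionSuvrs
```

`runPipeline(defaultConfig())` chains every stage (simulate → PVC → SUVR →
mixed models → voxelwise clusters → survival) into a run directory with CSV
tables, a structured log, and a JSON manifest; identical config and seed
give byte-identical outputs. A thin CLI (`inst/scripts/longpet`) exposes the
stages as `simulate`, `pvc`, `suvr`, `lmm`, `voxelwise`, `survival`, and
`run-all` subcommands.

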