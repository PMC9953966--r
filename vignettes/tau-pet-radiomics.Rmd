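---
title: "Tau PET radiomics: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tau PET radiomics: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tauradiomics` implements a complete radiomics workflow for group
classification of tau PET volumes: data-driven region-of-interest (ROI)
definition, Lloyd-Max intensity quantization, a 43-feature texture bank,
two-stage feature selection, and a linear-SVM evaluation harness, together
with SUVR and clinical-score comparator models and a synthetic phantom
generator that makes the whole chain testable without patient data.

This vignette documents the statistical model, the default parameters and
their rationale, and the behaviour of the pipeline in corner cases.

## The statistical model

The pipeline addresses a two-group classification problem (e.g. Alzheimer's
disease patients vs normal controls) from spatially normalized,
intensity-comparable 3D PET volumes sampled on a common grid with an
integer-labeled anatomical parcellation (an AAL-style atlas). The stages
are strictly ordered, and every stage that estimates anything does so on
training subjects only:

1. **Split first.** Subjects are split 70/30 into training and validation
   with stratification by group; externally acquired subjects are routed to
   a separate test role. The split precedes ROI definition so that no
   holdout voxel ever influences a trained object.
2. **ROI definition.** A voxelwise pooled-variance two-sample t-test over
   the training subjects, thresholded by the Benjamini-Hochberg procedure
   at FDR q < 0.01, followed by cluster-extent filtering (connected
   components at 18-connectivity, strictly more than 500 voxels), and
   mapping of surviving clusters onto atlas regions (at least 64
   overlapping voxels). The reference region is excluded.
3. **Quantization.** Uptake inside each ROI of each subject is discretized
   to 64 gray levels with the Lloyd-Max minimum-MSE quantizer. Because the
   quantizer is fit per subject and per ROI, the level maps — and therefore
   all downstream features — are invariant to affine rescaling of a
   subject's intensities.
4. **Texture features.** Per ROI, 3 histogram moments on the quantized
   levels plus 40 texture features: 9 from the gray-level co-occurrence
   matrix (13 unique 3D directions, symmetrized), 13 from the run-length
   matrix (same 13 directions), 13 from the size-zone matrix
   (26-connectivity zones), and 5 from the neighborhood gray-tone
   difference matrix (26-neighborhoods). With 60 ROIs this yields
   60 × 43 = 2580 feature columns.
5. **Selection.** A pairwise redundancy filter drops one member (by a
   seeded coin flip) of every feature pair with |Pearson r| > 0.1, then a
   pooled two-sample t-test keeps survivors with p < 0.005. Both run on
   training rows only.
6. **Classification.** A linear SVM (cost 1) under 5-fold stratified
   cross-validation repeated 100 times. Age and sex are regressed out of
   every feature using coefficients fit on the training rows. Holdout
   subjects are scored by averaging the five fold-models' decision values
   within each repetition, giving per-repetition holdout metrics
   (accuracy, sensitivity, specificity, and rank-based AUC).

The comparator models replace stage 3–5 by a single mean-uptake ratio per
ROI against the cerebellar reference (SUVR) or by the MMSE score alone
(clinical), then reuse the identical stage-6 harness.

## Synthetic cohorts

`cohort_spec()`/`generate_cohort()` produce a phantom study: a Voronoi
parcellation of an ellipsoidal "brain" into 61 regions (60 candidate ROIs
plus a cerebellum-like reference), and per-subject volumes consisting of a
baseline uptake, a smooth unit-variance Gaussian random field (white noise
smoothed to 4 mm FWHM and renormalized), plus injected patient effects:

- a crisp mean shift (default `mean_shift = 2` intensity units) in the 12
  affected regions, and
- a texture effect: inside affected regions the field is blended with an
  independent, more coarsely smoothed field, changing local spatial
  correlation without changing the mean.

Patient subgroups (tau status, ApoE carriership) modulate the effect
amplitude, so subgroup tasks (tau+ vs tau−) are also learnable. External
subjects receive an affine site shift. Everything derives deterministically
from one integer seed.

Two generator-related defaults deserve explanation:

- **No re-smoothing of simulated volumes.** The generator emulates PET that
  is already preprocessed (smoothed, spatially normalized), so the pipeline
  default is `fwhm = 0` for simulated cohorts and 8 mm for volumes read
  from disk. Re-smoothing the phantom with 8 mm bleeds the crisp injected
  shift into neighboring parcels and manufactures false-positive ROIs that
  are artifacts of double smoothing.
- **No covariate effects on uptake by default.** Age and sex affect only
  the manifest; setting them nonzero (supported) creates brain-wide group
  differences that confound the ROI-recovery properties.

## Corner-case behaviour

- **Null cohorts.** When no voxel survives FDR + extent thresholding, ROI
  definition falls back to the full parcellation with a warning (or returns
  an empty set with `fallback = "none"`). When no feature passes the t
  screen, the single smallest-p feature is retained and flagged
  (`fallback_used`). Both fallbacks only trigger under the null and keep
  end-to-end accuracy at chance, which is exactly what the null-calibration
  tests verify.
- **Degenerate ROIs.** ROIs below 27 voxels yield `NA` features with a
  warning; constant-intensity ROIs yield the degenerate single-level
  quantizer and the corresponding closed-form feature values.
- **Holdout metrics.** Cross-validated metrics on label-permuted data are
  pessimistically biased below chance (the usual anticorrelation of
  overfit folds); the unbiased chance checks therefore read the validation
  holdout, not the CV folds.

## Known limitations

- **The redundancy filter is extremely aggressive by design.** At
  |r| > 0.1, even a few hundred independent noise features collapse to a
  handful of survivors at n ≈ 80, and informative features — which
  correlate with each other through the group effect — collapse to roughly
  one representative. The radiomics model therefore often rides on a
  single feature. This is intentional and matches the published operating
  point, but it caps synthetic-benchmark accuracy near the single-feature
  ceiling.
- **Quantized features cannot see a pure mean shift.** Because
  quantization is per subject and per ROI, histogram and texture features
  are invariant to region-wide additive shifts; radiomics learns only from
  the texture effect. Conversely ROI-mean SUVR averages the voxel-level
  shift over hundreds of voxels and approaches a performance ceiling in
  the phantom, which has no subject-level affine intensity nuisance. On
  synthetic benchmarks at the default sizes the model ranking
  radiomics ≥ SUVR can therefore invert relative to clinical cohorts,
  where scanner and metabolism nuisance penalizes absolute-intensity
  models. The acceptance suite encodes the expected ranking faithfully and
  reports the observed one rather than tuning the generator to force it.
- Volumes are processed in memory as dense arrays; grids much beyond
  128³ × hundreds of subjects will be slow on one core.

## Reproducing the headline numbers

```{r}
library(tauradiomics)

cfg <- pipeline_config(seed = 1)        # default synthetic study, 60/60
res <- run_pipeline(cfg, out_dir = "run1")
report_table(res$reports)
```

`scripts/acceptance.R --seed 1 --out acceptance.json` recomputes the
structural counts, oracle agreements, null calibration, effect recovery and
leakage guard in one pass against the installed package.
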