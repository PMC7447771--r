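# radrobust

Radiomics promises quantitative imaging biomarkers, but every feature
computed inside a manually drawn tumor contour inherits the uncertainty of
that contour. `radrobust` implements the standard study design for
quantifying this on 3D MRI: several observers independently segment each
tumor, spatial agreement is measured with the volumetric Dice similarity
coefficient, features are extracted per (tumor, observer) pair with
IBSI-style definitions, and each feature is classified as robust or not by
its intraclass correlation across observers. Because multi-observer patient
datasets are rarely shareable, the package also ships a seeded synthetic
phantom cohort — two segmentation-difficulty classes of contrast-enhancing
breast-lesion look-alikes with simulated observers — so the entire analysis
is reproducible end to end from a single seed.

It is aimed at radiomics methodologists and imaging scientists who need
either (a) the robustness statistics for their own multi-observer feature
tables, or (b) a controlled sandbox in which segmentation variability is a
tunable quantity.

## The statistics at the core

**Dice similarity coefficient** between two segmentations A and B as voxel
sets:

    DSC = 2 |A ∩ B| / (|A| + |B|)

computed for all observer pairs per tumor (1 = perfect overlap, 0 =
disjoint; DSC > 0.7 is conventionally good overlap).

**ICC(2,1)** — two-way random-effects, absolute-agreement, single-measure
intraclass correlation — from the two-way ANOVA mean squares of the
n tumors × k observers matrix of one feature:

    ICC = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE))

where MSR, MSC, MSE are the subject (tumor), rater (observer) and residual
mean squares. A feature is **robust** iff ICC > 0.9 (strict). Features
whose modal value covers ≥ 95% of all records are removed beforehand as
near-zero-variance. Easy- and challenging-to-segment strata are compared
with Welch's t-test on per-tumor mean DSC.

Feature extraction covers shape (mesh-based, marching tetrahedra),
first-order statistics, and the GLCM / GLRLM / GLSZM / NGTDM / GLDM texture
families, on the original image and optionally on the 8 sub-bands of a
single-level stationary Haar wavelet transform, after z-score
normalization, isotropic 1 mm resampling, and fixed-bin-width
discretization (width 0.1, with the 16–128-bin selection rule available).

## Worked example

```r
library(radrobust)

cfg <- run_config(n_easy = 4, n_challenging = 2, n_observers = 3, seed = 7,
                  extraction = extraction_config(wavelet_enabled = FALSE))
res <- run_pipeline(cfg, out_dir = "radrobust_out", quiet = TRUE)

cat("Mean pairwise DSC:", round(res$cohort_summary$mean_dsc, 3), "\n")
cat("Easy vs challenging DSC:",
    round(res$comparison$mean_dsc_easy, 3), "vs",
    round(res$comparison$mean_dsc_challenging, 3),
    sprintf("(Welch p = %.3g)\n", res$comparison$p_value))
ov <- res$report$overall
cat("Mean ICC(2,1):", round(ov$mean_icc, 3),
    sprintf("(95%% CI %.3f-%.3f)\n", ov$ci_low, ov$ci_high))
cat("Robust features (ICC > 0.9):",
    format_robust_pct(ov$robust_count, ov$total_count), "\n")
```

prints

```
Mean pairwise DSC: 0.832
Easy vs challenging DSC: 0.851 vs 0.793 (Welch p = 0.305)
Mean ICC(2,1): 0.877 (95% CI 0.840-0.915)
Robust features (ICC > 0.9): 71.2% (74/104)
```

Six tumors agree at DSC ≈ 0.83 — the good-overlap regime of real
four-observer breast-MRI studies — and 71% of the 104 unfiltered features
survive the ICC > 0.9 cutoff; the easy stratum overlaps better than the
challenging one, though with 6 tumors the Welch test is (correctly) not yet
significant. `run_pipeline()` also writes `dsc_pairs.csv`,
`icc_per_feature.csv`, `group_summary.csv`, `stratified_summary.csv`,
`comparison.json` and a `run.log` into the output directory. Identical
config + seed gives byte-identical outputs.

A command-line wrapper lives at `inst/cli/radrobust.R`
(`simulate | extract | analyze | run` over NIfTI cohorts on disk).

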