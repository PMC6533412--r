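# gojrad

Whole-tumour PET/MRI radiomics for oesophageal / gastroesophageal-junction
(GOJ) cancer phenotyping, built around a small exploratory question: do
texture features of the primary tumour, computed from simultaneous
^18F-FDG-PET and MRI, separate patients with contemporaneous metastases
(M1) from those without (M0)?

The package is aimed at imaging scientists who want the whole analysis —
feature extraction, unsupervised feature-pair selection, discriminant
boundary, significance testing and segmentation-robustness checks — as
tested, reusable R functions rather than one-off scripts. Because no
patient images are distributed with it, a synthetic phantom generator
reproduces the study design end to end: 20 labelled multi-modal tumour
volumes whose texture structure carries (or, under a null preset, does not
carry) the class effect.

## What it computes

**Features.** For each case, up to five co-registered volumes (PET SUV,
T1-weighted, T2-weighted, high-b diffusion, ADC) share one binary tumour
mask. Per modality the package computes 12 first-order histogram features
(mean, SD, median, min, max, 10th/90th percentile, entropy, uniformity,
excess kurtosis, skewness, coefficient of variation) and 12 second-order
features of the grey-level co-occurrence matrix (GLCM): entropy, contrast,
homogeneity, homogeneity normalized, angular second moment, joint maximum,
joint average, joint variance, inverse difference, inverse difference
normalized, correlation, autocorrelation. The GLCM is 3-D (13 directions at
Chebyshev distance 1, symmetrized, counts merged before normalization) on
64 grey levels binned over the in-tumour range; entropies are in bits.
Three clinical comparators are carried alongside: SUV_max, ADC_mean and the
maximum 3-D (Feret) tumour diameter in mm.

**Selection.** Every unordered pair of feature columns is clustered with
k-means (k = 2, squared Euclidean distance, z-scored features, 25 seeded
restarts); the two clusters are mapped to the M0/M1 labels *a posteriori*
in whichever way maximizes agreement. Pairs are ranked by mapped accuracy,
ties broken by smaller Wilks' Λ.

**Inference.** For a selected pair `(e_ADC, e_SUV)` a classical
pooled-covariance LDA yields the boundary

    K + L1·e_ADC + L2·e_SUV = 0,

with the metastatic class on the strictly negative side, and a two-group
MANOVA tests mean-vector separation via Wilks' Λ (equivalently Hotelling's
T²; for two groups `F = ((n−d−1)/d)(1−Λ)/Λ` is exact). Diagnostic metrics
(SN, SP, PPV, NPV, ACC) come from the confusion matrix.

**Robustness.** Each mask is dilated and eroded by one voxel
(26-connected); all features are re-extracted (with discretization edges
frozen from the original ROI) and compared through relative error and the
intraclass correlation coefficient ICC(2,1) (two-way random effects,
absolute agreement).

## Worked example

```r
library(gojrad)

# 10 metastatic + 10 non-metastatic phantoms; the metastatic template has
# smoother SUV texture (low GLCM entropy) and rougher ADC texture (high
# GLCM entropy)
coh <- generate_cohort(cohort_preset("strong", seed = 1))
tab <- extract_cohort_features(coh)

round(tapply(tab$suv_glcm_entropy, tab$metastatic, mean), 2)
#> FALSE  TRUE
#> 10.35  9.12
round(tapply(tab$adc_glcm_entropy, tab$metastatic, mean), 2)
#> FALSE  TRUE
#>  9.11 10.31

res <- screen_pair(tab, "suv_glcm_entropy", "adc_glcm_entropy", seed = 1)
round(res$metrics)
#>  sn  sp ppv npv acc
#> 100 100 100 100 100
sprintf("Wilks lambda = %.4f, MANOVA p = %.2e", res$wilks_lambda, res$manova_p)
#> "Wilks lambda = 0.0137, MANOVA p = 1.46e-16"

fit_lda(cbind(tab$adc_glcm_entropy, tab$suv_glcm_entropy), tab$metastatic)
#> <discriminant_boundary> 391.4 -126.8*x1 +86.22*x2 = 0 (metastatic: < 0)
```

The planted signature is recovered with perfect within-sample diagnostics
on this synthetic cohort, and the fitted boundary has the same sign
structure as the clinically reported rule (negative ADC-entropy
coefficient, positive SUV-entropy coefficient: high ADC entropy combined
with low SUV entropy lands a case in the metastatic half-plane). A
comparator screen on SUV_max alone reaches only 60% accuracy here
(`screen_single_feature(tab$suv_max, tab$metastatic, seed = 1)`).

The full pipeline — extraction, exhaustive 7140-pair screen, LDA,
comparators and the perturbation study, with all artifacts written to disk
— is one call:

```r
run_pipeline(load_run_config(overrides = list(seed = 7)), out_dir = "run7")
```

or, from a shell, `Rscript inst/scripts/gojrad.R --synthetic strong --seed 7
--out run7`. Outputs: `features.csv`, `screen.csv`, `perturbation.csv`,
`report.json`, `run.log`; identical config + seed gives byte-identical
outputs.

## Limitations

The phantoms emulate texture-entropy structure, not anatomy: ellipsoidal
tumours, stationary Gaussian-derived textures with a rank-pinned marginal,
no acquisition physics. See the methods vignette
(`vignettes/gojrad-methods.Rmd`) for the generative model, the numerical
conventions, and what synthetic recovery does and does not demonstrate
about clinical data.
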