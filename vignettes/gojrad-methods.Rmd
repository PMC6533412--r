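---
title: "Methods: whole-tumour PET/MRI radiomics with gojrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-tumour PET/MRI radiomics with gojrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, conventions and
design choices: what is computed, under which assumptions, which knobs
matter, and where the genuinely open decisions were made. Every empirical
claim below is recomputed by the test suite or by
`scripts/acceptance.R`; nothing here reports a number the shipped code
does not produce.

## 1. The analysis

One case is a set of co-registered 3-D volumes (PET standardized uptake
value, T1-weighted, T2-weighted, high-b diffusion-weighted, and ADC) with a
single binary whole-tumour mask on the same voxel grid, plus a binary
metastasis label (M0/M1). The pipeline is:

1. **Feature extraction** per modality: 12 first-order histogram features
   and 12 second-order grey-level co-occurrence (GLCM) features, plus the
   clinical comparators SUV_max, ADC_mean and the maximum 3-D Feret
   diameter of the mask.
2. **Unsupervised pair screening**: every unordered pair of feature
   columns is clustered with k-means (k = 2); clusters are mapped to the
   labels a posteriori; pairs are ranked.
3. **Discrimination and inference**: classical LDA on a selected pair,
   reported in the form `K + L1·e_ADC + L2·e_SUV = 0` with the metastatic
   class in the strictly negative half-plane; two-group MANOVA via Wilks'
   Λ; confusion-matrix diagnostics (SN, SP, PPV, NPV, ACC).
4. **Segmentation-perturbation robustness**: one-voxel dilation and
   erosion of each mask, relative feature errors, and ICC(2,1) between
   original and perturbed feature values.

The intended sample-size regime is tiny (n ≈ 20), which shapes several
choices below: no more than two features are ever combined, there is no
cross-validation or multiplicity correction in the screen (deliberately —
the screen is exploratory and reported as such), and all stochastic steps
are seeded and restarted to be effectively deterministic.

## 2. Feature conventions

All conventions are fixed once, package-wide, and tested:

* **Discretization** (`discretization_config()`): fixed *bin number*
  (default `n_bins = 64`) over the in-ROI `[min, max]`, for all
  modalities. Fixed bin number keeps entropy magnitudes comparable across
  modalities whose absolute calibrations differ (SUV is unitless, ADC is
  in 10⁻³ mm²/s, MRI intensities are arbitrary), which matters for a
  screen that mixes modalities. The maximum maps to the top level; a
  constant ROI maps to level 1.
* **GLCM**: 3-D, Chebyshev distance 1 (13 unique direction vectors),
  pairs counted only when both voxels are in the mask, symmetrized by
  adding the transpose, counts merged across directions and then
  normalized (`glcm_policy = "merged"`). A per-direction
  feature-averaging policy (`"averaged"`) is available; merged is the
  default because it is the simpler object to state, test and reason
  about. A single-voxel mask has no pairs and is a hard error.
* **Entropy** is always log base 2 (bits) with `0·log 0 ≡ 0`. The base
  only rescales values and never reorders cases, but it must be pinned
  for reproducibility.
* **Moments** use population (N) denominators; kurtosis is excess
  kurtosis. With ROIs of a few thousand voxels the N vs N−1 distinction
  is negligible, but population moments make small hand-computed test
  fixtures exact. Skewness and kurtosis of a constant ROI are undefined
  and returned as `NA`; the coefficient of variation is `NA` when the
  mean is 0 (never infinity).
* **Percentiles** use linear interpolation between order statistics
  (`quantile` type 7), a named, testable rule.
* **Homogeneity nomenclature**: "homogeneity" is the inverse difference
  moment `Σ p/(1+(i−j)²)` and "homogeneity normalized" its
  range-normalized variant; "inverse difference" `Σ p/(1+|i−j|)` and its
  normalized variant are the separate features 21–22. This is the
  standard nomenclature split when all four appear in one feature list.
* **DWI** features are computed on the b = 900 s/mm² image, the
  conventional high-b texture substrate.
* **Maximum diameter** is the largest Euclidean distance between
  foreground voxel centres, in mm, computed over boundary voxels only.
  This is exact, not an approximation: a distance maximum is attained at
  points that are extreme in some direction, and a voxel with all 26
  neighbours inside the mask lies strictly inside the convex hull of its
  neighbours, so no interior voxel can be extreme. The equivalence is
  tested against an all-pairs brute force.

Missing modalities are tolerated at load time and produce `NA` feature
cells; operations that need those cells fail or skip per-feature, never at
cohort load. (The analogous clinical situation — individual sequences
unusable for technical reasons — is common enough that hard failure at
I/O would be wrong.)

## 3. The screen

Features are z-scored before clustering (`standardize = TRUE`). Raw
squared-Euclidean distance is scale-dependent, and a cross-modality search
over features whose native scales differ by orders of magnitude is
meaningless without it; a raw-scale mode is kept as an option. k-means
uses `stats::kmeans` with 25 restarts and at most 300 iterations,
seeded per pair (derived deterministically from the global seed), so the
screen does not depend on evaluation order. The cluster→label mapping
maximizes agreement, so mapped accuracy is ≥ 0.5 by construction, and the
clustering itself never sees the labels (permuting labels changes metrics
but not assignments — this is tested).

Pairs are ranked by mapped accuracy, ties broken by smaller Wilks' Λ of
the two *label* groups on the standardized pair, then lexicographically.
One property of this key deserves an honest flag. The 24-feature set is
highly redundant: most second-order features are smooth functionals of
the same local-similarity structure, so pairs of strongly correlated
features from one modality can show tiny Wilks' Λ purely because their
within-class scatter is nearly one-dimensional (the Mahalanobis
separation is inflated by a factor ≈ 1/(1−r²) for within-class
correlation r). When the class effect is strong enough that many pairs
tie at accuracy 1.0, this tie-break therefore tends to surface collinear
same-family pairs ahead of the scientifically interesting complementary
cross-modality pair. The acceptance script reports the rank of the
(SUV GLCM entropy, ADC GLCM entropy) pair for transparency; on the strong
synthetic preset that pair carries perfect diagnostics and a MANOVA p far
below 10⁻³ but is *not* rank 1 under this key. We kept the key as
designed rather than engineering a variant that favours the expected
winner; a screen intended for production use should consider penalizing
within-pair redundancy.

## 4. Discriminant boundary and MANOVA

`fit_lda()` is classical two-class LDA: pooled within-class covariance,
empirical priors, no shrinkage (n = 20, d = 2 is well-posed). The
boundary is reported unnormalized as `K + L1·x1 + L2·x2 = 0`; the overall
scale of `(K, L1, L2)` is not identifiable from the rule itself
(classification is invariant to positive rescaling — tested), so only the
form and the sign convention are meaningful: coefficients are oriented so
the metastatic class mean satisfies `K + L1·x1 + L2·x2 < 0`, and a point
exactly on the boundary is non-metastatic (the metastatic half-plane is
strictly open). In the headline application `x1` is ADC GLCM entropy and
`x2` SUV GLCM entropy, giving a negative `L1` and positive `L2` —
high-ADC-entropy, low-SUV-entropy cases land in the metastatic
half-plane.

`manova_two_group()` computes Wilks' Λ = det(W)/det(W+B) with the exact
two-group transform `F = ((n−d−1)/d)(1−Λ)/Λ` on `(d, n−d−1)` degrees of
freedom. The identities Λ = 1/(1 + T²/(n−2)) (Hotelling) and, for d = 1,
F = t² (pooled t-test) are asserted in the tests, along with agreement
with `stats::manova` and a 1000-replicate Gaussian null simulation of the
nominal type-I error.

Because cluster partitions and LDA partitions need not coincide, the run
report carries the diagnostic metrics of the top pair twice — from the
k-means mapping and from the fitted LDA rule — plus a
`partitions_agree` flag, instead of silently choosing one.

## 5. The phantom generator

`generate_phantom()` builds, per modality, a texture field

    image = mean + amplitude · field + noise,  noise ~ N(0, noise_sd²),

where `field` is seeded white noise convolved with an isotropic Gaussian
kernel of standard deviation `corr_length_mm` (the correlation length ℓ,
in mm), standardized inside the ellipsoidal tumour mask. Longer ℓ means
locally smoother texture and lower GLCM entropy; that is the single knob
the class presets turn. Defaults place the modality means and amplitudes
in plausible clinical ranges (SUV 8 ± 2 for an FDG-avid tumour, ADC
1.5 ± 0.4 ×10⁻³ mm²/s), on a 32×32×24 grid at 2 mm isotropic spacing with
semi-axes 18×14×20 mm — a few-cm primary tumour of ~2600 voxels.

Two refinements matter and are worth their own paragraphs:

**Rank-pinned marginal.** After smoothing, the in-mask values are replaced
by their normal scores (exact N(0,1) quantiles in rank order). Without
this, the fixed-bin-number discretization couples the histogram *shape*
to ℓ — smoother fields have fewer in-mask extremes, a tighter range, and
therefore a more uniform binned histogram — and the marginal effect can
cancel or even invert the intended monotone ℓ → entropy response. With
the marginal pinned, ℓ changes only the spatial arrangement: first-order
features carry no class signal by construction, and mean GLCM entropy
decreases monotonically in ℓ (tested over seeds, including the paired
1 mm vs 8 mm ordering). A consequence worth knowing: phantom skewness and
kurtosis are near their Gaussian values on every case, so *relative*
errors on these near-zero features are not meaningful summaries (see §7).

**Two-scale mixing options.** `phantom_config()` accepts an optional
rough component (`rough_length_mm`, with `mixing` ∈ `"sum"`, `"zonal"`,
`"zonal_level"`, `"level_mod"`, `"zone_mod"`) that combines a smooth and
a rough field either pointwise (jointly Gaussian) or in spatial zones
(a variance mixture with the same autocovariance). These constructions
exist to probe how strongly the second-order features co-move: mixtures
with matched second moments still move the difference-sensitive features
(homogeneity, inverse difference) at least as much as entropy, which is
the measured basis for the screening caveat in §3. The presets do not use
them.

`generate_cohort()` draws per-case parameter jitter (default ±15%
uniform, applied multiplicatively to means, amplitudes, correlation
lengths, noise SDs and tumour semi-axes) and a per-case phantom seed from
a stream seeded with `cohort_seed + case_index`, so cohorts are
bit-reproducible and stable under appending cases. The presets differ
only in how the SUV/ADC correlation lengths split between classes:
`strong` (6 mm vs 1.2 mm, mirrored between modalities so metastatic cases
have smooth SUV and rough ADC), `moderate` (4 vs 2), `null` (3 vs 3 — no
class difference, for false-positive-rate testing). Effect sizes cannot
be calibrated against the clinical study (it reports no per-class feature
values); `strong` is designed so the planted signature is recovered with
headline-strength diagnostics, `null` so that nothing is.

**What the phantoms do not emulate:** anatomy (tumours are ellipsoids),
acquisition physics (no partial-volume, bias fields, or motion),
inter-modality registration error, and realistic inter-patient
heterogeneity (within-class variation is parameter jitter plus field
randomness). Passing synthetic recovery therefore demonstrates that the
*pipeline* is correct and sensitive to the texture contrast it targets —
not that the clinical effect exists or would replicate.

## 6. Perturbation study conventions

Masks are dilated/eroded one iteration with a 26-connected 3×3×3
structuring element ("one voxel" is read direction-agnostically; the
6-connected cross is available by config). An erosion that removes the
whole tumour excludes that case from the erosion arm with a warning.

Feature re-extraction under perturbed masks freezes the discretization
bin edges at the original ROI's `[min, max]` (out-of-range values clamp
to the end bins). Re-estimating edges on the perturbed ROI lets erosion
— which strips the shell containing the in-mask extremes — contract the
bin width and systematically inflate entropy-family features; the frozen
edges isolate what the study is about, segmentation *geometry*, from
bin-width re-estimation. With this convention the GLCM-entropy ICCs on
the strong preset exceed 0.97 in all four modality × mode arms (computed
by the acceptance script).

ICC is fixed to ICC(2,1): two-way random effects, absolute agreement,
single measurement, treating {original, perturbed} as two raters over
cases. Absolute agreement is the stringent variant — a systematic offset
between original and perturbed values lowers it (tested against a
from-scratch ANOVA decomposition). It is reported as `NA` when the
between-case variance vanishes. Relative feature error uses
`|Δf|/|f_orig|·100` with baselines below `eps = 1e-8` excluded; volume
change is `|ΔV|/V·100`, spacing-free on a shared grid, and reported per
perturbation mode (the artifact has one mask per case, so per-modality
volume changes would be copies).

## 7. Problem sizes, tolerances and degenerate inputs

* Oracle equivalences (GLCM features vs brute-force double sums, ICC vs
  ANOVA) are asserted at 1e−10; algebraic identities (Λ–T², F = t²) at
  1e−10 or tighter; hand-computed fixtures exactly.
* The MANOVA type-I calibration uses 1000 replicate null-preset cohorts
  of 5+5 cases on a reduced 16×16×12 grid — the calibration of an exact
  F-test does not depend on the class sizes, and the reduced grid keeps
  the study at a few minutes while leaving ~400 in-mask voxels per case.
  Observed rejection at α = 0.05 is required within 3–7%.
* Unit tests use 16×16×12 phantom grids (≈ 700-voxel tumours); the
  acceptance checks use the full 32×32×24 study conditions.
* Degenerate inputs have defined behaviour throughout: constant ROIs
  (entropy 0, uniformity 1, single-cell GLCM), single-voxel masks
  (diameter 0, GLCM error), empty masks (construction error), zero-mean
  ROIs (CoV `NA`), ties on the discriminant boundary (non-metastatic),
  constant screening columns (skipped with a message), vanishing erosions
  (excluded with a warning), near-zero error baselines (excluded).
* Mean ± SD relative feature error aggregated over *all* features is
  dominated by sign-indefinite, near-zero-baseline features (skewness,
  correlation) on these phantoms; the per-feature table in
  `perturbation.csv` is the informative output, and the acceptance
  script reports the entropy-specific errors.

## 8. Known limitations

* The clinical study's discretization, GLCM dimensionality, distance and
  direction handling are unreported; the conventions here are reasoned
  defaults, not reconstructions, so absolute feature values are not
  comparable to the original in-house software — only the pipeline's
  structure and qualitative behaviour are.
* The printed boundary coefficients (K = 40.90, L1 = −7.75, L2 = 6.25)
  live on the original patients' feature scale and cannot be reproduced
  without those data; the package reproduces the *rule* (tested by direct
  substitution) and the sign structure on synthetic cohorts.
* The screen performs no selection inference; with 7140 pairs and n = 20
  its top accuracies are optimistic by construction. The MANOVA p-value
  is calibrated for a *prespecified* pair (the null-preset study), not
  for the selected maximum.
* Resampling between PET and MRI grids is out of scope: each case must
  arrive on one shared grid.
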