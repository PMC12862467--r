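---
title: "Margin-band radiomics with omrad: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-band radiomics with omrad: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omrad)
```

## The problem

Microvascular invasion (MVI) in hepatocellular carcinoma is a
histopathologic finding available only after resection, yet it drives
recurrence risk and would ideally inform treatment before surgery. The
tumor margin — the transition zone where tumor infiltrates surrounding
parenchyma — is where the imaging correlates of invasion are expected to
live. `omrad` implements a margin-band radiomics workflow for
hepatobiliary-phase MRI (or any 3D scalar volume with a lesion mask):

1. construct every inner-erosion/outer-expansion margin band on an integer
   millimetre sweep (121 volumes of interest per lesion for a 0–10 mm
   sweep, counting the unmodified lesion);
2. compute a curated set of texture and shape features on each band under
   logarithm, Laplacian-of-Gaussian and stationary-wavelet filters;
3. run nine feature-selection chains on every band, rank the resulting
   models by internal-test AUC, and call the winning band the *optimal
   margin region* (OMR);
4. split patients at the maximum-Youden cutoff of the winning signature
   and quantify the split with Kaplan–Meier/log-rank survival analysis and
   contingency-table association tests.

## The model

For a lesion mask $M$ on a 1 mm isotropic grid, the band with inner
erosion $a$ and outer expansion $b$ (both integer mm) is

$$B_{a,b} \;=\; \big(M \oplus \mathcal{B}_b\big) \setminus \big(M \ominus \mathcal{B}_a\big),$$

with $\mathcal{B}_r$ the Euclidean ball of radius $r$. Both operations are
computed from the exact Euclidean distance transform, so bands are
rotation-invariant: erosion keeps voxels deeper than $a$ from the
complement, dilation adds outside voxels within $b$ of the mask. The
$(a{=}0, b{=}0)$ pair is the empty set; the whole lesion is a distinct
121st region. The field reports bands as "outer $b$ mm, inner $a$ mm":
the OMR reported for MVI in HCC is outer 0 mm / inner 5 mm — the inner
5 mm rim of the tumor.

The signature on a band is an $\ell_1$-then-stepwise (or other chain)
reduction of the feature set followed by a maximum-likelihood logistic
model on standardized features; the *radiomics score* is the linear
predictor. ROC, AUC, and the Youden cutoff are invariant to the logistic
link, so working on the log-odds scale loses nothing.

The grid search evaluates each (band, chain) pair on the training cohort
only, refits the final signature on the full training cohort, and scores
the internal-test cohort, which never enters selection, standardization or
fitting. Ranking is by internal-test AUC; ties resolve to the higher
training cross-validated AUC, then to the narrower band (the unmodified
lesion counts as the widest). Each chain draws one derived seed shared
across all bands, so every region is judged under identical fold
randomness and the ranking cannot depend on evaluation order.

## Features

Seven features are first-class, named by filter, class and statistic:

| name | region | meaning |
|---|---|---|
| `logarithm_firstorder_Minimum` | band | darkest voxel after dynamic-range compression |
| `logarithm_glcm_Imc1` | band | informational measure of correlation 1 (≤ 0) |
| `original_shape_Elongation` | lesion | $\sqrt{\lambda_2/\lambda_1}$ of the coordinate covariance |
| `wavelet_LHL_glcm_MCC` | band | maximal correlation coefficient of the co-occurrence matrix |
| `wavelet_HLH_ngtdm_Busyness` | band | rate of local gray-tone change |
| `log_sigma_3_0_mm_3D_glcm_ClusterShade` | band | skewness of the co-occurrence distribution |
| `wavelet_HHH_glcm_JointEntropy` | band | randomness of gray-level pairs |

GLCMs are symmetric, computed at Chebyshev distance 1 over the 13 unique
3D directions, features averaged per direction. NGTDM uses 26-connectivity
with neighbours outside the region excluded from the mean. Shape features
always use the original lesion mask — a band is a shell whose principal
axes say nothing about the tumor.

Numerical conventions for degenerate regions (flat intensity, single
voxel) follow the dominant radiomics implementations so that phantom edge
cases do not crash pipelines: joint entropy 0, cluster shade 0, IMC1 0,
MCC 1, busyness 0. The registry is extensible by name; full parity with
the ~2000-feature catalogues of general-purpose radiomics engines is a
non-goal.

## Tunable parameters and their defaults

* **Working grid 1.0 mm isotropic, trilinear for images / nearest for
  masks.** Millimetre band widths are only meaningful on an isotropic
  grid; 1 mm makes mm equal to voxel. The source acquisition's grid and
  interpolation order are not dictated by the method, so this is a
  package choice, fixed in one place.
* **Sweep step 1 mm, range 0–10 mm.** An integer sweep over
  $[0,10]^2$ minus the empty pair reproduces the 120-band count; the
  sweep maximum is configurable.
* **Discretization: fixed bin width 25 intensity units, min-anchored.**
  The common radiomics default; min-anchoring makes every texture feature
  invariant to intensity shifts. On strongly smoothed filter outputs
  (e.g. the 3 mm LoG of a quiet region) the in-band range can fall below
  one bin width; the degenerate conventions above then apply.
* **LoG $\sigma$ = 3.0 mm**, truncated at $3.5\sigma$; computed as the sum
  over axes of sampled-Gaussian separable convolutions with a DC-corrected
  second-derivative kernel, so constants map exactly to zero and a bright
  blob yields a negative centre response.
* **Wavelet family Coiflet-1, single-level stationary transform, periodic
  boundary.** The subband names fix only the filter sequence, not the
  family; Coiflet-1 is the de-facto radiomics default. Periodic boundary
  handling makes the transform exactly invertible by its adjoint, which
  the test suite exploits.
* **ICC variant: two-way random effects, absolute agreement, single
  measurement**, retention strictly above 0.75. The reproducibility
  literature's ICC(A,1); the variant is a package choice.
* **Chain hyperparameters.** Correlation pruning at $|r| > 0.90$ keeping
  the feature more correlated with the label; univariate Wald screening at
  $p < .05$; lasso penalty by 10-fold cross-validation under the 1-SE
  rule; stepwise bidirectional by AIC, capped at 30 steps; tree/SVM stages
  act as importance pre-rankers keeping the top $\min(20, p)$ before the
  lasso. The gradient-boosting ranker runs through xgboost configured as a
  classic stochastic GBM (depth-2 trees, learning rate 0.1, 50%
  subsampling).
* **Separable training data** fall back to a ridge penalty of $10^{-4}$
  with a message; the Youden cutoff and risk groups are unaffected by the
  link scale.
* **Association-test rule.** 2×2 tables with all expected counts ≥ 5 use
  the Yates-corrected chi-square; larger tables with all expected ≥ 5 the
  plain Pearson chi-square; any expected count < 5 switches to Fisher's
  exact test. P values print to three decimals, with values above .999
  shown as ">.999". This rule reproduces standard clinical-software
  output.

## The phantom cohort

Real hepatobiliary-phase MRI with outcome labels cannot ship with a
package, so `generate_cohort()` simulates the study conditions end to end:
bright smooth liver background (mean 120, SD 10), darker ellipsoidal
lesion (mean 80, SD 10; semi-axes uniform on 11–15 mm — solitary tumors
just over 2 cm), a planted margin band (default inner 5 mm / outer 0 mm)
whose label-1 noise variance ramps linearly with depth from baseline at
the lesion surface to `effect_size`²-fold at the band's deep edge, and
label-coupled exponential survival (hazard ratio 3, median 60 months OS /
40 months DFS in the label-0 class) under independent uniform censoring on
12–84 months. Labels are Bernoulli(0.4), the typical MVI prevalence
bracket; the 70/30 train/internal-test split is recorded in the cohort
table. An optional zero-intensity cavity adjacent to a configurable
fraction of lesions exercises the nontarget-tissue flagging.

Three design choices deserve explanation because they decide what the
phantom can and cannot validate:

* **The effect is a variance (texture) difference, not a mean shift.** Six
  of the seven curated features are texture/signal statistics; a mean
  shift would be found by a trivial first-order feature and would say
  nothing about the texture machinery.
* **The effect ramps with depth and sits on patient-level nuisance
  variability.** A spatially uniform rim effect makes every sub-band of
  the rim carry the full signal, so the planted band is not identifiable —
  any 1 mm sliver of the rim separates the classes as well as the whole
  rim does. The depth ramp makes shallow sub-bands weak; lognormal
  per-patient texture scales on the whole volume (SD 0.2), the tumor core
  (SD 0.35) and the parenchyma (SD 0.7) keep the AUC off its ceiling and
  actively penalize volumes of interest that reach beyond the margin zone
  into label-irrelevant tissue. This mirrors the biological claim the
  margin-region method rests on: the transition zone is informative, core
  and parenchyma are patient-specific noise.
* **Survival is coupled to the true label, not to the score**, so
  stratification power flows through MVI prediction, reproducing the
  study's causal logic (MVI → prognosis) rather than baking in a
  score–survival association.

What passing phantom tests shows: the geometry, features, selection
machinery, ranking and stratification recover a known planted optimum
under realistic noise. What it does not show: performance on real MRI,
where acquisition physics, segmentation error, and biological
heterogeneity are not captured; the phantom has no motion or bias-field
artifacts and a single "sequence".

## Problem sizes

The shipped test-suite and acceptance-script runs use: the full
9-chain × 121-region grid on a 60-patient phantom; planted-band recovery
on 240-patient cohorts over the reduced sweep (inner, outer ∈ 0..6) with
the two stepwise-pruned chains, repeated over seeds; a 300-patient null
cohort (effect 1.0) for cross-validation calibration; and 400 × 50
tabular designs for selection-chain support recovery. These sizes were
chosen so a complete validation runs on a laptop in tens of minutes while
keeping every statistical check adequately powered.

## Numerical notes

* The distance transform is the exact Felzenszwalb–Huttenlocher squared
  EDT; band membership uses squared-distance comparisons, so no
  floating-point square roots enter the geometry.
* GLCM statistics are accumulated in C++; MCC uses the identity
  $Q = (D^{-1}P)^2$ with $D$ the diagonal of marginals, so its
  eigenvalues are the squared eigenvalues of a symmetric similarity,
  computed by cyclic Jacobi iteration.
* Ranking keys map NA (unscored models) below every real value; the
  ranked table is therefore total and deterministic.
* Every stage derives its RNG seed from the master seed and a stage
  label, restoring the caller's RNG state afterwards; identical
  configurations reproduce byte-identical reports.
* NIfTI-1 stores geometry in float32, so spacing/origin round-trip to
  single precision there; voxel data and the NRRD header round-trip in
  full double precision.

## Known limitations

* Only axis-aligned grids are supported in the readers; DICOM series,
  bias-field correction and cross-scanner intensity harmonization are out
  of scope.
* The 2060-feature catalogue of general-purpose engines is not
  reproduced; the registry covers the seven curated features plus basic
  first-order statistics.
* Morphology is 3D; slice-wise 2D workflows are not offered.
* The false-discovery-rate-adjusted AUC variant reported alongside some
  published results has no described procedure and is not implemented.
* Cohort-level published AUCs are not reproducible without the original
  MRI; the phantom validates the machinery, not the clinical effect size.
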