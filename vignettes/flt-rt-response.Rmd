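---
title: "Modelling early FLT-PET response to radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling early FLT-PET response to radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fltrt)
```

## The problem

[18F]fluorothymidine (FLT) is a PET tracer whose uptake follows thymidine
kinase 1 activity, a surrogate for the S-phase fraction and hence tumour
proliferation. In non-small cell lung cancer treated with radiotherapy
(RT) alone, a decrease in lesion FLT uptake after one to two weeks of
treatment is a candidate early pharmacodynamic end point. Two statistical
questions decide whether that read-out is usable:

1. **Repeatability** — how much do volume, SUV_mean and SUV_max vary
   between two scans of the same untreated lesion? A treatment effect is
   only interpretable if it exceeds this noise floor.
2. **Effect estimation with clustered lesions** — patients carry one
   primary tumour and a variable number of malignant nodes. Lesion-level
   changes are therefore not independent, and primary tumours and nodes
   may respond differently.

This package implements the full chain — image quantification, test-retest
analysis, response calculation, and a random-intercept offset ANCOVA —
together with a synthetic cohort generator that reproduces the exact
statistical structure the models assume, so every stage is testable
without access to patient images.

## SUV quantification

Activity images in kBq/ml are normalized voxelwise to standardized uptake
values, `SUV = A_corr * weight / dose`, where `A_corr` is the activity
decay-corrected to injection time (`A * 2^(t / 109.77)` for F-18 when the
scanner has not already applied the correction). Injection-time reference
is the universal SUV convention; a tissue density of 1 g/ml is implicit in
the unit cancellation, so 1 kBq/ml at a dose-to-weight ratio of 1 MBq/kg
gives SUV 1.0 in g/ml.

Per-lesion statistics are taken over voxel-aligned binary masks sharing
the image grid exactly: `volume_cm3` from the voxel count, `suv_mean` and
`suv_max` over the mask. Fractional (partial-volume) masks are
deliberately unsupported — delineation and registration are upstream of
this package, and mis-registration is handled only through a QC check
that counts lesion voxels inside, or within a face-connected margin of, a
bone mask. Bone marrow proliferates and takes up FLT strongly, so the
default QC tolerates zero overlapping voxels.

Gaussian smoothing (default FWHM 4 mm, the clinical post-reconstruction
filter) is a separable zero-padded convolution with `sigma = FWHM/2.3548`
per axis, converted to voxel units; the kernel is truncated at 4 sigma and
renormalized, conserving image mass away from edges. Whether smoothing
precedes or follows SUV normalization is immaterial — both operations are
linear and commute.

## Test-retest repeatability

For duplicate baselines the percentage difference is
`d = (Scan2 - Scan1)/(Scan1 + Scan2) * 200`, antisymmetric and bounded in
(-200, 200). Reproducibility is the sample SD of `d` across lesions, the
absolute reproducibility its mean absolute value, and the repeatability
coefficient `RC = 1.96 * SD`. A response is called a true change only when
it falls strictly outside `bias ± RC` (the interval is closed: a value on
the boundary stays "within" — the conservative call).

Two grouping conventions exist for the SD: across lesions (default,
matching the reported group sizes of 7 primaries and 11 nodes) or across
patient means; `summarize_reproducibility(averaging = "patient")` selects
the latter. Volume repeatability is size-dependent (small lesions are
proportionally harder to delineate reproducibly), so volume RCs are
applied per lesion type while SUV RCs are pooled across types — the
`size_dependence()` diagnostic (Spearman correlation between |d| and mean
lesion size) motivates this choice on any given cohort.

## The offset ANCOVA

Let `y0_ij`, `y1_ij` be a lesion's pre/post values (model A: the two
baselines; model B: latest baseline and the on-treatment scan). The model

```
log10(y1_ij) = log10(y0_ij) + (beta0 + b_i) + beta1 * x1_ij + eps_ij
```

fixes the baseline coefficient at 1, so inference concerns the log-ratio
`z_ij = log10(y1_ij / y0_ij)`: `beta0` is the mean log change for primary
tumours, `beta0 + beta1` for nodes, `b_i ~ N(0, sigma_b^2)` absorbs
patient-level heterogeneity shared by a patient's lesions, and
`eps_ij ~ N(0, sigma^2)` is lesion-level noise. Back-transformation
`10^beta - 1` converts effects to relative changes; the variance partition
`sigma_b^2 / (sigma_b^2 + sigma^2)` says how much of the residual
variation is patient-level.

**Estimation.** Maximum likelihood, by profiling the variance ratio
`lambda = sigma_b^2 / sigma^2`: at fixed `lambda` the per-patient
covariance blocks `I + lambda * J` invert in closed form, so GLS gives
`beta` and `sigma^2` analytically, and a deterministic bounded search
(`optimize`, tolerance 1e-9, `lambda` in [0, 200]) maximizes the profile
log-likelihood — bit-stable fits with no iterative convergence failures.
ML rather than REML is the default so the AIC cleanly counts all four
parameters `(beta0, beta1, sigma_b^2, sigma^2)`; `method = "REML"` is
available for variance-component reporting. The tests verify the optimum
against a dense 2-D grid-search oracle (|delta logLik| < 1e-6) and against
`nlme::lme` to four decimals.

**Inference.** Wald CIs on the log10 scale, back-transformed
endpoint-wise (symmetric in log space, wider above after
back-transformation because `10^x` is convex). The normal reference is
the default; `ci_method = "t"` substitutes a t quantile with
`n_lesions - p` degrees of freedom for small cohorts, where Wald-normal
intervals undercover somewhat (the parameter-recovery suite measures
coverage of roughly 90-95% at 12 patients). `lambda` is bounded at zero;
boundary estimates are reported with a flag and no boundary correction is
applied to the fixed-effect p-values — a documented limitation. When all
patients carry a single lesion, `sigma_b^2` is unidentifiable and the fit
flags it; when a cohort has one lesion type, `beta1` is dropped (k = 3).
Lesions missing a required scan are dropped listwise per model.

**BED covariate.** `fit_ancova_with_covariate()` adds a linear fixed
effect of biologically effective dose, `BED = n D (1 + D/(alpha/beta))`
with `alpha/beta = 10` Gy (the tumour convention) and `n` the fractions
delivered before the response scan, and reports
`delta AIC = AIC(extended) - AIC(base)`; a constant covariate is refused
as collinear. Per-lesion dosimetry is exposed but schedules default to
per-patient, since nodal doses are rarely reported separately.

## Rank statistics and outcome analysis

Spearman's rho (average ranks, two-sided p via the t approximation with
n-2 df, standard at the study's n of 18-48) backs the baseline correlation
matrix and the size-dependence diagnostic; an exact permutation p (full
enumeration, feasible to n = 10, implemented in C++) is available for
small samples. The rank-sum test uses the exact Mann-Whitney null when
n1 + n2 <= 20 without ties, otherwise a tie-corrected normal approximation
with continuity correction. No multiple-testing correction is applied
anywhere — the analysis is exploratory by design.

Outcome analysis is deliberately univariate: Kaplan-Meier curves with
Greenwood/log(-log) confidence limits and the median as the earliest time
the curve reaches 0.5, plus Cox regression on a single continuous
covariate (Newton-Raphson on the partial likelihood, Efron ties by
default — generally less biased than Breslow, and identical without
ties). Monotone likelihoods (perfect separation) are flagged rather than
silently returned. Dichotomizing patients at an uptake cut-point is
intentionally unsupported: at a dozen patients, cut-point selection
dominates the answer.

## The synthetic cohort generator

`generate_cohort()` draws, from one seeded stream in documented order:
per patient the nodal lesion count (uniform over the configured range)
and the random intercept(s); per lesion and parameter a lognormal
baseline, two independent test-retest noise draws (S1, S2), and the
on-treatment value `log10(S3) = log10(S2) + beta0 + b_i + beta1*node +
eps`. Presets encode the study conditions:

* `cohort_config_response()`: 12 patients, 1-2 nodes each (~30 lesions),
  baseline lognormal moments matched to the reported response-cohort
  means/SDs (e.g. primary SUV_mean 2.2 ± 0.7, node 1.7 ± 0.4), model-B
  effects per parameter (SUV_mean beta0 = -0.127, beta1 = -0.095,
  sigma_b^2 = 0.00224, sigma^2 = 0.00556, and analogously for SUV_max and
  volume).
* `cohort_config_reproducibility()`: 7 patients, null effects, retest
  noise `sqrt((sigma_b^2 + sigma^2)/2)` per parameter from the
  duplicate-baseline variance components (0.047-0.058 log10 units),
  consistent with the reported Eq.-2-scale SDs via the delta method.

Each parameter gets an independent `b_i` by default (the three parameters
are modelled separately); `share_random_intercept = TRUE` couples them.
The generator emulates the *statistical* structure only: no PET physics
(attenuation, scatter, reconstruction), no respiratory motion, no
partial-volume coupling between shrinking volume and measured uptake, and
no delineation variability. Passing tests therefore demonstrate that the
estimators recover the assumed model at the study's scale — not that the
model captures every feature of real scans.

`generate_phantom()` complements this at the voxel level: ellipsoidal
lesions and a bone-marrow box on a uniform background at scanner geometry
(2.67 x 2.67 x 2.00 mm voxels), smoothed and noised, with pre-smoothing
masks as ground truth; overlapping lesions are an error because their
ground truth would be ambiguous. Survival records come from exponential
event times with log-hazard linear in on-treatment SUV_max and
independent exponential censoring calibrated to a target fraction under
the null (under a non-null link the realized censoring fraction shifts
with the covariate).

## Problem sizes and numerical choices

The test suite runs the estimators at the study's own scale (12 patients,
~30 lesions) for the parameter-recovery and coverage suites (200
simulated cohorts), uses cohorts of 1500-2000 patients where a law of
large numbers is being checked, 10^4 null replicates for the exact
rank-sum size check, and exhaustive enumeration oracles at n = 7 (5040
permutations) and C(10,5) = 252 label assignments. Grid-search oracles
use 50 x 50 grids over (lambda, sigma^2) and a 1e-4-step grid over the
Cox coefficient. Convergence tolerances: 1e-9 on the ANCOVA profile
search, 1e-10 on the Cox score. The phantom default grid (64 x 64 x 48)
keeps the separable convolution well under a second.

## Known limitations

* Wald inference throughout; no likelihood-ratio or boundary-corrected
  tests for variance components.
* No registration, segmentation, reconstruction or partial-volume
  correction — the package starts from aligned images and masks.
* The generator cannot reproduce per-lesion values of the original
  cohort (only summary moments were reported), so comparisons to the
  published per-lesion scatter are out of reach by construction.
* Printed clinical CIs were somewhat wider than Wald-normal intervals
  from the printed SEs suggest; the original CI method is unstated, so
  both normal and t flavours are provided rather than guessing.
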