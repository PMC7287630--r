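---
title: "Methods: voxel-count logistic classification of task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-count logistic classification of task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case/control imaging studies often reduce a subject-level statistical map
(here, a voxelwise t-map from a working-memory task contrast) to one number
per anatomical region: the count of voxels whose t-statistic strictly
exceeds a threshold. With an Automated Anatomical Labeling (AAL)-style
parcellation of about 117 regions, each subject becomes a 117-vector of
non-negative integers, and classification of disease status (here, Gulf War
Illness cases against sedentary controls, with exercise-defined orthostatic
phenotype subgroups among cases) becomes a small-n, moderate-p supervised
learning problem. `roilogit` implements that pipeline end-to-end and, because
the original imaging data are not publicly deposited, ships a synthetic
cohort generator so every stage can be validated against planted truth.

## The model

The classifier is the logistic model

$$ p(x) = \frac{1}{1 + e^{-(\beta_0 + \beta_1 x_1 + \dots + \beta_i x_i)}} $$

over region voxel counts $x_i$, with age (years), sex (male indicator) and
BMI (kg/m²) always included as covariates and never eliminated. Coefficients
maximize the binomial log-likelihood. The default solver is deterministic
iteratively-reweighted least squares; an SGD mode (stochastic epochs
followed by a Newton polish) is provided for fidelity to
gradient-descent-trained descriptions of the same model. Both must leave the
score (log-likelihood gradient) below `1e-6` in max-norm at the returned
optimum, which the tests verify against an independent multi-start BFGS
optimizer. Three-class (subgroup) problems are fitted one-vs-rest, one
coefficient set per class over a shared feature support, mirroring how the
published subgroup tables print three coefficient columns per region.

Feature reduction has two gates:

1. **Collinearity screen.** Pearson correlations between region features are
   computed on the training split, the test split, and the full table; a
   region failing $|R| \ge 0.9$ against an earlier-retained region in any of
   the three is dropped globally. The elimination rule (drop the
   later-ordered member; use $|R|$ rather than signed $R$) is a package
   choice where the source procedure is underdetermined: elimination is
   deterministic and reversible via the report, and strong negative
   correlation is exactly as collinear as strong positive correlation.
2. **Recursive feature elimination.** Backward greedy elimination drops one
   feature per round, importance being the absolute standardized coefficient
   $|\hat\beta_j| \cdot \mathrm{sd}(x_j)$ (class-averaged for multi-class).
   The retained count is the size along the elimination path maximizing
   inner stratified cross-validated accuracy, ties broken toward fewer
   features. RFE runs on the training partition only by default (matching
   the described sequence of the source procedure); nested per-fold
   selection can be had by calling it inside your own fold loop, at the
   usual cost and benefit.

Evaluation uses stratified train/test splits with largest-remainder
rounding (so 111 subjects split 80/31 at 70:30 give exactly 78 = 56 + 22
training subjects), a 50:50–90:10 ratio search with a lowest-SD tie-break,
and stratified 10-fold cross-validation. Classification is at probability
0.5 with the exact tie assigned to the negative (control) class — an
arbitrary but deterministic convention. Reports carry the full confusion
matrix (TP/FP/TN/FN) plus accuracy, sensitivity, specificity, PPV and NPV as
their defining ratios; "accuracy" is always the fraction correct. Wald
p-values from the observed information are Sidak-adjusted,
$p \mapsto 1-(1-p)^m$ with $m$ the number of regions in the final model.

Significance of a fitted pipeline is assessed by the **shuffle test**:
outcome labels are permuted uniformly, the *entire* build (fresh stratified
split, screen, RFE, fit, held-out accuracy) is re-run per permutation, and
the empirical p-value is the fraction of permutations whose accuracy reaches
the observed one. The default estimator is `exceedances / n_runs` — matching
the published arithmetic in which 49 of 1000 shuffled runs yields
p = 0.049 < 0.05 — with the $(k+1)/(n+1)$ small-sample variant behind
`plus_one = TRUE`. If no run reaches the observed accuracy after `n = 1000`
permutations, the test escalates and continues to `max_n = 10000`. Per-run
seeds come from a counter-based child-seed scheme: runs are mutually
independent yet the whole test reproduces bit-for-bit from one seed.

## The synthetic world

`cohort_spec()` defaults state the cohort the pipeline was designed around:
80 cases vs. 31 controls, 117 regions, case subgroups 23/46/11
(START/STOPP/POTS), age 46.9 ± 7.8 (cases) vs. 43.9 ± 16.3 (controls) years,
BMI 29.6 ± 5.6 vs. 28.4 ± 4.5 kg/m², male proportions 0.738 vs. 0.613.
Counts are negative binomial — non-negative and overdispersed, with the
Poisson as the large-`dispersion` limit — because the source material never
states a count distribution; `baseline_mean = 30` expected suprathreshold
voxels per region and `dispersion = 2` (variance $\mu + \mu^2/2$, SD ≈ 16 at
the default mean) were chosen once as realistic for ~100-voxel-scale AAL
regions thresholded at t > 3.17, and are not tuned thereafter. Age and BMI
are truncated normal (18–90 years, 15–60 kg/m²) since only moments are
published; sex is Bernoulli. Requested inter-region correlations are induced
through a Gaussian copula, which preserves the negative-binomial marginals
but attenuates the latent correlation somewhat on the count scale — the
tests therefore assert strong, not exact, induced correlation. Subgroups are
an independent categorical label over cases with their own effect maps,
because the real phenotypes are defined physiologically (heart-rate
response), not statistically.

`generate_statmaps()` builds voxel maps *jointly* with their count table:
background voxels are drawn from a standard normal truncated at the
threshold and exactly the tabled number of voxels per region receive values
from the tail above it. This deliberately skips raw BOLD simulation and
first-level GLM estimation (out of scope upstream stages) while making
extraction exactly invertible — the round-trip equality
`build_feature_table(generate_statmaps(...)) == table` is the package's
strongest extraction oracle. A green round-trip therefore establishes
correct counting, not realistic spatial autocorrelation, smoothness, or
registration error, none of which the generator emulates.

## Numerical choices

- **Strict threshold inequality**: a voxel at exactly t = 3.17 is not
  counted ("exceeding" the cut). The normal-reference upper tail at 3.17 is
  ≈ 7.6e-4 < 1e-3; the degrees of freedom behind the original "p < 0.001"
  labeling are never asserted.
- **Separation**: with p ≈ n or planted perfect predictors the binomial
  likelihood has no finite optimum; the fit warns and returns a
  ridge-stabilized refit (λ = 1e-3, intercept unpenalized). Resampling
  helpers suppress that warning deliberately — the stabilized refit *is* the
  intended behaviour inside CV loops.
- **Zero-variance features** are flagged in the correlation matrix (not
  silent `NaN`) and exempted from the screen; they carry no information and
  standardized-coefficient importance ranks them first for elimination.
- **Determinism**: every randomized operation takes a seed and restores the
  global RNG state; identical spec + seed reproduce tables, maps, splits,
  folds and permutation runs bitwise.

## Why the null-calibration check uses the full region set

A pure-null cohort at 80/31 has a majority-class rate of 0.72. A
nearly-intercept-only logistic model (few noise features) predicts the
majority class and scores ≈ 0.72 under CV — "chance" for an imbalanced
problem, but outside a 0.5 ± 0.1 band. The package's calibration check
instead runs CV with the pipeline's actual downstream input, all 117
regions: with p > n the (ridge-stabilized) fit interpolates the training
folds and its held-out predictions decorrelate from both truth and the
training prevalence, landing the measured mean near 0.52 over 50 seeds —
inside the band. Both readings are reported here so a green check is not
over-interpreted: it establishes that the overparameterized pipeline carries
no spurious signal, not that every sub-model is calibrated to 0.5 under
class imbalance.

## Known limitations

- The minimal NIfTI-1 layer reads/writes uncompressed single-file `.nii`
  with an sform affine (datatypes uint8/int16/int32/float32/float64); no
  `.nii.gz`, qform-only files, or resampling — maps and atlas must share the
  voxel grid exactly, as the upstream preprocessing guarantees.
- The shipped printed-model fixtures support structural assertions
  (counts, overlaps, extremes, subset relations, intercept evaluation), not
  refitting: the underlying per-subject data are not available.
- One-vs-rest is the only multi-class parameterization; a softmax variant
  would not change any of the structural table assertions.
- The published headline accuracies (70.6% Day 1, 85.3% Day 2) are narrative
  context only; nothing in this package claims to reproduce them.
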