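---
title: "Predicting cognitive performance from brain metabolism: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cognitive performance from brain metabolism: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(petgpr)
```

## The scientific problem

Neurodevelopmental disorders such as neurofibromatosis type 1 (NF1)
produce heterogeneous cognitive deficits whose biological substrate is
unclear. One way to probe that substrate is to ask whether an
individual's cognitive performance can be *predicted* from their
resting-state brain glucose metabolism, measured voxelwise with
18F-FDG PET. Because a neuropsychological battery contains many
overlapping tests, the battery is first summarised by principal
components; each leading component is then regressed on the whole-brain
metabolic pattern with a multivariate model, and predictive accuracy is
assessed by leave-one-out cross-validation (LOOCV) with a permutation
test for significance. The multivariate weight map — one signed weight
per voxel — localises the metabolic pattern that carries the
prediction.

`petgpr` implements this pipeline end to end. Since clinical PET scans
cannot be redistributed, the package ships a synthetic-cohort generator
with a known planted signal, so every stage can be validated against
ground truth.

## The model

With subjects' in-mask voxel values collected in the rows of
$X \in \mathbb{R}^{n\times p}$ ($p \gg n$) and a target $y$ (a
principal-component score), the package fits Gaussian-process
regression with the linear ("vanilla") kernel $k(x,x') = x\cdot x'$.
Targets are centred by their training mean $\bar y$ and the dual
coefficients solve

$$(K + \sigma^2 I)\,\alpha = y - \bar y, \qquad K = XX^\top,$$

so all linear algebra is $n\times n$ (a Cholesky factorisation; a
single jitter of $10^{-10}\,\mathrm{tr}(K)/n$ is added with a warning
if the factorisation fails). Predictions are
$\hat y_* = \bar y + X_* X^\top\alpha$ and the primal voxel weights are
$w = X^\top\alpha$, which makes the model exactly equivalent to ridge
(Bayesian linear) regression with penalty $\sigma^2$ — an equivalence
the test suite checks against explicit primal solves.

Target centring deserves a note: a zero-mean linear kernel on
residualized features cannot express an intercept, so without centring
the model would be biased for any target with non-zero mean.

### Noise variance

The noise variance defaults to $\sigma^2 = 0.001$, the conventional
fixed setting for this analysis on globally scaled features. Type-II
maximum likelihood tuning is provided (`optimize_noise()`, or
`sigma2 = "optimize"` in `run_pipeline()`): a deterministic 1-D bounded
maximisation of the log marginal likelihood over $\log\sigma^2$ with
termination tolerance 0.001. It is off by default because the fixed
value is the reference condition; the evidence path exists for
sensitivity analyses.

## Preprocessing

The pipeline order is fixed and enforced by a stage tag on the feature
matrix: smooth → downsample → mask/vectorize → global-mean scale →
age-residualize.

* **Smoothing** — separable Gaussian, per-axis
  $\sigma_{\text{vox}} = (\mathrm{FWHM}/\text{voxel size})/(2\sqrt{2\ln 2})$,
  default FWHM 12 mm. The kernel is truncated at $3\sigma$ and
  renormalised; the boundary replicates the nearest voxel. These two
  choices make constant volumes exactly invariant and preserve the
  total sum away from the boundary.
* **Downsampling** — each output voxel is the mean of a 2×2×2 input
  block; odd trailing slices are dropped (floor), which is the only
  reading consistent with a 91×109×91 grid mapping to 45×54×45. An
  in-plane 2×2 reading ("4 adjacent voxels") cannot reproduce those
  output dimensions. The brain mask is downsampled by ≥ 50 % block
  occupancy.
* **Vectorization** — in-mask voxels in R's column-major raster order
  (first axis fastest), 1-based coordinates, with an explicit
  column-to-(i,j,k) index so weight vectors can be painted back.
* **Global-mean scaling** — each subject's row divided by its mean
  over in-mask voxels (the vector is defined after masking), removing
  global-signal differences; rows end with mean exactly 1 and the
  operation is idempotent.
* **Age residualization** — per voxel, OLS of scaled uptake on
  (intercept, age); the GP is trained on the residuals because age has
  a strong global and regional effect on metabolism that would
  otherwise dominate the kernel.

### Why residualization is fold-safe by default

If the age regression is fit once on the full sample, every residual
column sums to zero across subjects, so the held-out subject's feature
row is *exactly* the negative sum of the training rows. Substituting
this identity into the GP equations collapses the LOOCV prediction to
$\bar y_{\text{train}} + \sigma^2\sum_i\alpha_i$, whose first term is
anti-correlated with the held-out target and whose second term is
noise amplified by the near-null Gram direction. Empirically a strong
planted signal then yields LOOCV $r \approx -0.17$ where the fold-safe
variant yields $r \approx 0.94$. `run_pipeline()` therefore refits the
residualization inside every training fold by default
(`fold_safe = TRUE`), applying the training-fold coefficients to the
held-out subject; the full-sample mode remains available for
comparison. This is a leakage question only for the *observed*
statistic — the permutation test is internally valid in either mode,
because permuted and observed targets are processed identically.

## Battery PCA

Scores are optionally log-transformed (base 10; dexterity completion
times are right-skewed), z-scored with the $n-1$ variance, and
decomposed by SVD. The log base is immaterial: any base yields the
same standardized column, which the tests assert. Components are
ordered by decreasing variance; each loading column is sign-flipped so
its largest-magnitude entry is positive (SVD signs are arbitrary;
fixing them makes results deterministic). With unit-norm loadings the
contribution of measure $j$ to component $k$ is $100\,\ell_{jk}^2$ %,
summing to 100 per component, with $100/17 \approx 5.88$ % as the
expected-average reference for the default 17-measure battery. The
battery is configuration-driven (a data frame or YAML list of measure
names plus log flags), so custom batteries share all code paths. No
factor rotation and no missing-data imputation are provided; subjects
with incomplete data are expected to be excluded upstream.

## Cross-validation and inference

LOOCV refits the GP on each leave-one-out training set; in the fixed
$\sigma^2$, full-sample-residualization mode the Gram matrix is
computed once and folds reuse its submatrices. Accuracy is the Pearson
correlation between observed and predicted values, which is rejected
as undefined (rather than silently NA) for constant vectors.

The permutation test shuffles *targets only* (feature rows, and the
residualized features, are never recomputed under permutation), reruns
the complete LOOCV per draw and reports $p = \#\{r_b \ge r_{\text{obs}}\}/B$,
one-sided by default since the hypothesis is accuracy above chance.
With this count/$B$ convention the smallest reportable positive value
at $B = 1000$ is exactly 0.001, and a zero count is reported as
"p < 1/B". Child seeds are derived from the master seed by a counter,
so enlarging $B$ never changes earlier draws. The identity permutation
is excluded only by chance. When several components are tested no
multiplicity correction is applied — deliberately mirroring common
practice for this design — so users testing many components should
adjust externally.

Weight maps average the $n$ per-fold primal weight vectors and paint
them onto the downsampled grid, zero outside the mask.

## The synthetic-cohort generator

The generator is the package's test bed, not a PET simulator. For
subject $i$ with age $a_i$ and latent cognitive factor
$g_i \sim N(0,1)$:

* scores: $s_{ij} = \lambda_j g_i + \varepsilon_{ij}$,
  $\varepsilon_{ij}\sim N(0, 0.6^2)$, loadings $\lambda_j = 0.8$;
* uptake: baseline 100 + (smooth spatial slope field, SD 0.2 per year)
  × $(a_i - \bar a)$ + $\beta\, g_i P_v$ + $N(0, 10^2)$ voxel noise,
  then 12 mm FWHM smoothing and flooring at $10^{-6}$ (with a warning)
  to keep uptake positive.

The defaults describe the emulated study condition: 16 subjects, ages
uniform on 8–44 years, a 24×28×24 grid of 8 mm voxels (the same field
of view as a 91×109×91 grid of 2 mm voxels at a test-friendly size),
an ellipsoidal brain mask with semi-axes 0.45 of each grid dimension,
and a two-lobe planted pattern $P_v$ (one +1 and one −1 ellipsoid of
radius 3 voxels) coupled to $g$ with $\beta = 8$ — an ~8 % metabolic
change per SD of the latent factor, a deliberately strong but not
absurd effect chosen once so that the planted signal is recoverable at
$n = 16$; no published effect size links metabolism to cognition in
this population, so $\beta$ is a test condition, not a biological
estimate. Setting $\beta = 0$ and all loadings to 0 gives exchangeable
null cohorts. Up to three latent factors with separate loading vectors
and ROI sets are supported to emulate multi-component batteries.

What the generator does *not* emulate: PET physics (attenuation,
scatter, reconstruction), anatomy, registration error, and non-linear
or non-Gaussian noise. Passing tests therefore demonstrate the
correctness and calibration of the *analysis*, not performance on real
scans.

## Numerical and design choices

* Cholesky solves everywhere; no explicit inverses or determinants.
  $\sigma^2 = 0$ is allowed only when the Gram matrix is invertible.
* Voxel coordinates are 1-based with R's column-major raster order,
  matching the rest of the R neuroimaging ecosystem.
* Sample ($n-1$) variances throughout.
* Ellipsoid masks accept radii larger than the grid (the mask is then
  the full grid); pattern ROIs, by contrast, must fit inside the grid.
* Degenerate inputs fail loudly: empty masks, non-positive global
  means, constant targets, zero-variance score columns, fewer than 3
  distinct ages, conflicting ROI signs.

## Problem sizes used in the validation suite

The test-bed sizes are chosen to exercise every code path at
interactive scale: null-calibration runs use 200 replicate cohorts of
16 subjects on a 20×24×20 grid with $B = 99$ permutations
(≈ 800 in-mask voxels after downsampling); signal-recovery runs use
the default 24×28×24 cohort. At these sizes the observed statistic is
exchangeable with its permutation null by construction, so the
rejection rate at $\alpha = 0.05$ has expectation exactly 0.05, and
the suite checks it against the corresponding exact binomial interval.

## Worked example

```{r example, eval = FALSE}
co  <- simulate_cohort(cohort_config(seed = 42))
rep <- run_pipeline(co, components = 1, B = 99, seed = 42)
print(rep)
#> FDG-PET -> cognition prediction pipeline
#>   16 subjects, 816 in-mask voxels, sigma2 = 0.001, B = 99
#>   PC1: LOOCV r = 0.924, p < 0.0101

truth <- downsample_by_two(co$pattern$volume)
wmap  <- rep$components$PC1$weight_map
cosine_similarity(wmap[rep$mask], truth[rep$mask])
#> [1] 0.8345411
```

## Known limitations

* No spatial normalization/registration: volumes must already share a
  grid. Real studies need an external registration step first.
* The full-sample residualization mode reproduces a published order of
  operations but is degenerate for LOOCV (see above); it should only
  be used to study that degeneracy.
* Predictive variance is computed internally (`predict(..., se.fit =
  TRUE)`, `simulate()`) but the pipeline reports only point accuracy.
* Only the linear kernel is implemented; non-linear kernels would
  break the primal weight-map interpretation that motivates the
  method.
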