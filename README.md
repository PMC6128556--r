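# petgpr

Voxel-based prediction of cognitive performance from resting-state
brain metabolism (18F-FDG PET) with linear-kernel Gaussian-process
regression.

Cognitive deficits in conditions such as neurofibromatosis type 1 are
heterogeneous, and a natural question is whether an individual's
neuropsychological profile is expressed in their whole-brain metabolic
pattern. `petgpr` implements the standard analysis for that question:
a neuropsychological battery is summarised by principal components;
each leading component is predicted from the subjects' in-mask voxel
values by GP regression with the linear kernel; accuracy is measured
by leave-one-out cross-validation (LOOCV) and its significance by a
permutation test; and the fitted model is mapped back onto the brain
as a signed voxel weight map. The package is aimed at imaging groups
who want a tested, reproducible reference implementation of this
pipeline, together with a synthetic-cohort generator (patient scans
cannot be shared) that plants a known spatial signal so the whole
chain can be validated against ground truth.

## The model

With feature rows $X \in \mathbb{R}^{n \times p}$ ($n$ subjects,
$p$ in-mask voxels, $p \gg n$) and target $y$, the GP with kernel
$k(x, x') = x \cdot x'$ is fitted in the dual form

$$(XX^\top + \sigma^2 I)\,\alpha = y - \bar{y},$$

with predictions $\hat y_* = \bar y + X_* X^\top \alpha$ and primal
voxel weights $w = X^\top \alpha$ — exactly ridge regression with
penalty $\sigma^2$ (default 0.001; type-II maximum-likelihood tuning
available). Preprocessing applies 12 mm FWHM Gaussian smoothing,
factor-2 block downsampling, brain masking, global-mean scaling, and
voxelwise age residualization (refit within each training fold by
default).

## Worked example

```r
library(petgpr)

co  <- simulate_cohort(cohort_config(seed = 42))   # 16 subjects, planted signal
rep <- run_pipeline(co, components = 1, B = 99, seed = 42)
print(rep)
#> FDG-PET -> cognition prediction pipeline
#>   16 subjects, 816 in-mask voxels, sigma2 = 0.001, B = 99
#>   PC1: LOOCV r = 0.924, p < 0.0101
```

The cohort couples a latent cognitive factor to the 17 test scores and
to a two-lobe metabolic pattern (one hyper-, one hypometabolic
ellipsoid). The report says the first principal component of the
battery was predicted from the images with LOOCV Pearson r = 0.924,
and that none of 99 target permutations reached that accuracy
(p below the 1/99 resolution of the test). The recovered weight map
can be compared with the planted ground truth:

```r
truth <- downsample_by_two(co$pattern$volume)
wmap  <- rep$components$PC1$weight_map
cosine_similarity(wmap[rep$mask], truth[rep$mask])
#> [1] 0.8345411
```

Group-comparison statistics (pooled t, Cohen's d, chi-square) work
from raw tables or directly from printed summary statistics:

```r
pooled_t_from_summary(summary_row("Age", 25.56, 16.94, 16, 23.75, 11.77, 16))
#> Age: t(30) = 0.351, p = 0.728, d = 0.124
```

See `vignettes/methods.Rmd` for the model, the generator's design and
every numerical choice.

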