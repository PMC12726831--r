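# tbmorph

Transport-based morphometry (TBM) of volumetric lesion images in R.

The package addresses a problem from stroke imaging: predicting **hematoma
expansion** — growth of an intracerebral hemorrhage by ≥ 6 mL between the
presentation non-contrast CT and the 24 ± 6 h scan — from the morphology of
the presentation lesion alone. It is written for image-analysis researchers
who want a fully inspectable, desk-scale implementation of the method and a
synthetic-phantom harness to validate every stage without access-controlled
clinical data.

## The method

A segmented, windowed (0–150 HU), smoothed lesion image normalized to unit
total intensity is a probability measure. For a reference template `I₀` and
a subject image `I₁`, TBM computes the mass-preserving map `f` with

```
det(Df(x)) · I₁(f(x)) = I₀(x),   det(Df) ≥ 0,
```

minimizing the quadratic transport cost `∫ |f(x) − x|² I₀(x) dx`, whose
minimum is the squared Wasserstein distance `W₂²(I₀, I₁)`. Fixing `I₀` to
the cohort's intrinsic mean template makes each subject's map its **linear
optimal transport (LOT) embedding** `Î_k = f_k`: a vector on which linear
statistics work. The modeling stack is

* PCA retaining 95% of variance,
* a penalized Fisher discriminant (pLDA, ridge on within-class scatter) for
  the expansion label,
* the most-correlated direction (single-outcome CCA) for continuous growth
  (mL),
* optional augmentation with lesion location (the translation removed when
  centering each lesion on the template) and clinical covariates
  (age, sex, INR, IVH score), `a_k = [w_k | v]`,
* repeated stratified 60/40 train/validation splits with percentile CIs and
  Fisher-combined p-values.

Because the embedding is invertible, any point of the model space — e.g.
`X̄ + σ·w⁰` along the discriminant direction — can be synthesized back into
an image (`traverse_direction()`), which is how the morphology that drives
predicted expansion (larger size, density heterogeneity, shape
irregularity, peripheral density) is visualized.

## Worked example

```r
library(tbmorph)
coh <- make_cohort(cohort_spec(n = 40, grid = make_grid(32, 2),
                               effect_weights = c(size = 4, periph = 1.5),
                               noise_sd = 2, seed = 7))
fit <- tbm(coh, solver = solver_config(max_iters = 15), template_iters = 2)
summary(fit)
val <- run_repeated_splits(fit$embeddings, fit$labels, split_plan(10, seed = 3))
val
```

```
<tbm_cohort> n = 40, grid 32x32x32 @ 2x2x2 mm, expansion prevalence 0.20
Transport-based morphometry fit (n = 40)
  PCA: 5 components, 97.4% variance
  template: 2 iterations, mean cost 66.9382 -> 62.2900
  expansion prevalence: 0.20, covariates: none
  training AUROC 0.988, acc 0.925, sens 1.000, spec 0.906
  training growth correlation 0.851
<tbm_metrics> plda over 10 repeats
  auroc        0.951 [0.858, 1.000]
  accuracy     0.875 [0.812, 0.986]
  sensitivity  0.867 [0.667, 1.000]
  specificity  0.877 [0.769, 1.000]
  ppv          0.662 [0.500, 1.000]
  npv          0.968 [0.917, 1.000]
  combined p (Fisher): 1.66e-23
```

The cohort is 40 synthetic ellipsoidal hematomas on a 32³, 2 mm grid whose
simulated 24-hour growth is driven by lesion size and peripheral density
(plus 2 mL of noise). The fit estimates the intrinsic mean template (the
per-iteration mean transport cost, in mm², must not increase), embeds every
subject, and keeps the 5 leading principal components. Held-out AUROC 0.951
over ten 60/40 splits says the transport embedding recovers the planted
morphological signal at this effect size; with the label permuted the same
pipeline collapses to AUROC ≈ 0.5. `plot(fit)` renders
the traversal of the discriminant direction (σ = −2 … 2) as overlays on the
template, and `run_pipeline()` orchestrates the whole
simulate → fit → evaluate → visualize → power workflow into a
self-describing run directory.

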