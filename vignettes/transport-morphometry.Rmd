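---
title: "Transport-based morphometry of volumetric lesion images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport-based morphometry of volumetric lesion images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Transport-based morphometry (TBM) treats a segmented, intensity-normalized
lesion image as a probability measure: after windowing to the blood-density
range (0–150 HU), masking to the segmentation, curvature-driven smoothing and
normalization to unit total intensity, the image says *where the lesion's
mass sits*. Two such images are compared by optimal mass transport: the
mass-preserving (MP) deformation `f` satisfying

    det(Df(x)) I1(f(x)) = I0(x),   det(Df) >= 0,

that minimizes the quadratic cost `∫ |f(x) − x|² I0(x) dx`. The minimum is
the squared Wasserstein distance `W₂²(I0, I1)`. Fixing `I0` to a cohort
template turns each subject image `I_k` into its transport map `f_k` — the
linear optimal transport (LOT) embedding — on which ordinary linear
statistics are meaningful: Euclidean distances between embeddings approximate
transport distances between images, and any point of the embedding space can
be *inverted* back into an image, which is how fitted directions are
visualized.

In the motivating application the subjects are presentation non-contrast CT
scans of spontaneous intracerebral hemorrhage, the binary outcome is 24-hour
hematoma expansion (growth of at least 6 mL between the presentation and
24 ± 6 h scans, an inclusive threshold), and the continuous outcome is the
absolute volume change in mL. The morphology traits the method is expected to
surface are larger size, density heterogeneity, shape irregularity, and a
peripherally weighted density distribution.

The fitting surface is a single call:

```{r}
library(tbmorph)
coh <- make_cohort(cohort_spec(n = 60, grid = make_grid(32, 2),
                               effect_weights = c(size = 4, periph = 1.5),
                               seed = 1))
fit <- tbm(coh, covariates = "none")
summary(fit)
```

`tbm()` preprocesses every record, estimates the intrinsic mean template,
embeds each subject, reduces with PCA (components explaining 95% of the
variance), and fits a penalized Fisher discriminant (pLDA) for the expansion
label and the most-correlated direction (single-outcome CCA) for growth.
`predict()`, `coef()`, `plot()` and `traverse_direction()` operate on the
fitted object; `run_repeated_splits()` reproduces the repeated 60/40
train/validation protocol.

## The MP transport solver

The solver is a penalized variational method over a displacement field
`u = f − id` on the reference grid:

* **Objective.** Mass-weighted transport cost plus (i) the squared relative
  L2 residual of the MP constraint weighted by `mp_penalty` (default 1000),
  (ii) a curl penalty (default 1) nudging the field toward a gradient map,
  (iii) an elastic penalty on the displacement gradient (default 2) that
  suppresses grid-scale oscillation invisible to the data terms, (iv) a
  mass-weighted hinge barrier (default 1e5 below `det = 0.1`) that keeps the
  map orientation-preserving wherever there is mass to invert (folds in
  massless fringe regions are harmless and tolerated), and (v) a penalty on
  the squared total-mass deviation of the pushed-forward reference (default
  1e5) that pins global mass conservation to well below 0.1%. A tiny
  uniform "attachment" weight (1e-3 of total mass, spread over the grid)
  pins the field to zero where there is no mass to move; without it the CDF
  tails of the initialization inject arbitrary displacements into massless
  regions.
* **Initialization.** The separable product of the three 1D marginal CDF
  rearrangements, tapered to the identity where a marginal carries no mass.
  This is the exact optimal map for separable densities, so translate-type
  problems start essentially solved.
* **Optimization.** L-BFGS over a multiresolution pyramid (3 levels by
  default; a level is dropped when a side would fall below 8 voxels). The
  coarse detour helps strongly multimodal rearrangements but can leave a
  worse basin than the direct fine-grid rearrangement start, so the fine
  descent begins from whichever of the two has the lower objective. A final
  polish pass at the finest level hardens the MP penalty 100×, so the final
  accuracy is set by the constraint rather than by the cost/penalty
  trade-off. The objective and its exact analytic gradient (including the
  trilinear-interpolant partials) are evaluated in a C++ kernel; a pure-R
  reference implementation is kept and tested against it to machine
  precision. The solver has no stochastic step: identical inputs and
  configuration reproduce identical maps. Typical map accuracy against
  closed-form optima is 2–3% of the displacement magnitude; the packaged
  oracle checks therefore run at moderate (~4 voxel) displacements where
  the 0.1-voxel absolute criterion is meaningful.
* **Zero mass.** Both inputs are floored by `epsilon_floor = 1e-8` total
  mass spread uniformly before renormalization, making MP maps between
  disjoint supports well-posed.
* **Units.** Displacements are voxels of the reference grid;
  `transport_cost` is converted to mm² through the voxel spacing, and
  `wasserstein_distance()` reports mm.

Embeddings are the flattened displacement fields in the generative sign
convention `v(x) = x − f(x)`, so the same vector that represents a subject
can be handed to `invert_embedding()` — which forms `f_v = id − v`, inverts
it by a vectorized Newton iteration, and pulls the reference through
`I_v = (I0 / det(Df_v)) ∘ f_v⁻¹` — to resynthesize the subject. Using the
same trilinear interpolation and central-difference Jacobian as the solver
makes the round trip consistent to the solver's MP residual. The LOT
distance between embeddings is the unweighted L2 integral over the reference
domain, as the transport-space statistics assume; a √I0-weighted variant
common elsewhere in the LOT literature is deliberately not the default.

## Template estimation

The LOT reference is the intrinsic mean: starting from the Euclidean mean
`μ`, each iteration solves the MP maps that transform every subject into the
current template, averages the displacement fields voxelwise, and pulls the
current template through the averaged map
(`I0_new = det(Dfbar) · I0 ∘ fbar`). With a single image this reproduces
that image in one step; with two translated copies it converges to the
mid-position shape. Because averaged maps can fold, a folding update is
damped toward the identity (halving) until admissible, and an update that
fails to reduce the mean transport cost is rejected outright, so the
recorded per-iteration mean cost is non-increasing by construction. The
stopping rule (relative mean-cost change below `tol = 1e-3`, at most
`max_outer` iterations) is a package choice; no canonical stopping criterion
exists for this iteration.

## Transport-space statistics

* **PCA** retains the smallest number of components reaching 95% cumulative
  variance (`var_frac` adjustable); everything runs through the thin SVD
  because the embedding dimension (3 × grid voxels) vastly exceeds n.
* **pLDA** maximizes between- over within-class scatter with a ridge
  `S_W + λ tr(S_W)/p · I`; the relative scaling keeps the λ grid
  (10⁻³…10³) meaningful across data scales. λ is chosen by inner-split
  validation AUROC. The decision threshold is the equal-prior crossing of
  the two projected class Gaussians. The exact penalty form used in the
  original study is not public; ridge is the documented substitute.
* **CCA** with a single outcome reduces to the normalized least-squares
  direction `Cov(X)⁻¹ Cov(X, y)`, which maximizes the Pearson correlation
  between projection and outcome.
* **Location and clinical covariates.** Lesions can be translated so their
  center of mass coincides with the template center (integer-voxel shifts,
  hence exactly reversible and mask-preserving); the removed translation
  (mm) and the clinical vector (age, sex, INR, IVH score) are concatenated
  to the PCA scores, each column z-scored by training statistics only.
* **Validation.** `run_repeated_splits()` repeats stratified 60/40 splits
  (the study protocol prescribes 1000 repeats; tests use 25 for runtime),
  refits PCA and the model inside each training part, and aggregates
  validation metrics as means with percentile 95% CIs. Stratification is a
  deliberate deviation from plain shuffling: it prevents empty-class
  repeats; a redraw guard (max 10) covers residual degeneracy. Per-repeat
  p-values (projection t-test; correlation test) are combined by Fisher's
  method (χ² of −2Σlog p on 2k df). Two-sided α = 0.05 throughout.
* **Power.** `auc_power()` implements the Hanley–McNeil variance
  approximation with a normal test statistic; `auc_power_mc()` is the
  binormal Monte-Carlo cross-check used by the acceptance script.

## The phantom generator

`make_cohort()` synthesizes the study conditions: rotated ellipsoidal
lesions with a two-compartment radial density (core vs peripheral shell)
multiplied by a positive smoothed texture field, on a 2 mm, 32³ grid by
default. Latent factors per subject:

| factor | distribution | measured counterpart |
|---|---|---|
| size | base radius lognormal, median 12 mm, σ_log 0.3 | lesion volume |
| eccentricity | one-sided elongation `q = exp|N(0, 0.25)|`, volume-neutral | moment-tensor eccentricity |
| heterogeneity | texture amplitude U(0, 0.5), 6 mm correlation length | in-mask coefficient of variation |
| peripheral ratio | shell/core density U(0.8, 2.0), shell = outer quarter | shell/core mean-intensity ratio |
| location | center jitter N(0, 4 mm) per axis; effect = projection on a unit vector | translation covariate |

Growth is `intercept + Σ β_f z_f + N(0, noise_sd)` in mL with the latent
factors standardized, the label applies the 6 mL threshold, and the
intercept is tuned by bisection on a separate seeded stream of 5000
factor draws so the realized expansion prevalence matches the target (33%
by default, the derivation-cohort rate). Radii are lognormal with median
12 mm so volumes span roughly 7–100 mL at desk scale; clinical covariates
(age N(64.1, 12.45), sex Bernoulli(0.376), INR lognormal around 1.09, IVH
score Binomial(12, 0.12), treated as an opaque ordinal) are simulated
independently of the image factors so covariate-augmentation tests isolate
the image signal. Each subject draws from a private counter-derived stream,
so cohorts are reproducible and order-independent.

What the phantoms do *not* emulate: skulls, ventricles, partial-volume and
beam-hardening artifacts, registration error, segmentation noise, or any
coupling between clinical covariates and morphology. Passing tests therefore
demonstrate that the pipeline recovers planted morphological signal under
idealized imaging, not clinical performance.

## Numerical choices and degenerate inputs

* Windowing clamps (it does not delete) out-of-range voxels, preserving
  mask topology and total mass; whether the original protocol clamped or
  zeroed is not documented.
* Mirroring to one hemisphere is reflection about the midsagittal voxel
  plane; a center of mass exactly on the plane is not flipped, and the
  reflection is an exact involution on lesions that stay on-grid.
* The smoothing filter is explicit-Euler mean-curvature flow blended with a
  weak isotropic diffusion (weight 0.2): pure level-set motion leaves
  single-voxel extrema untouched (their gradient vanishes), while the blend
  smooths them monotonically; flat regions remain exact fixed points. Step
  0.125, 5 iterations.
* The interior-depth transform behind the peripheral density ratio is an
  iterative 6-connected erosion (integer depth); adequate for quartile
  banding, it is not an exact Euclidean distance transform.
* Degenerate inputs raise classed errors rather than returning silently:
  empty masks, all-zero volumes, non-normalized solver inputs, constant
  outcomes, single-class labels, folding displacement fields (reported with
  the worst voxel), and covariate missingness (no silent imputation).

## Problem sizes

The packaged validation runs at deliberately desk-scale sizes chosen to keep
a full check of the method honest but fast: transport oracles on 48³ grids,
round trips and the end-to-end cohort (n = 120) on 32³ grids at 2 mm
spacing with 25 repeated splits, and the location-effect comparison at
n = 60. The original study's preprocessing grid (150×190×120 at 1 mm after
template registration) and 1000 splits are reachable by configuration but
are not exercised in the tests.

## Known limitations

* The MP solver is a penalized local method: the constraint is satisfied to
  a residual (typically a few percent relative L2 at 32³), not exactly, and
  strongly multimodal rearrangements can settle in local optima. The
  oracles bound this behaviour where closed forms exist.
* Embeddings are compared on the full grid including massless regions;
  the attachment term keeps those regions near zero, but they still
  contribute weakly to PCA.
* The template is estimated on the full cohort before repeated splitting
  (as in the source protocol), so split metrics share the template; with
  n ≫ dimensionality of interest this leakage is negligible for the
  phantom checks, but a deployment would freeze the template on training
  data only.
* Clinician scoring systems, alternative ML baselines, skull stripping and
  inter-subject registration are outside the package's scope.
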