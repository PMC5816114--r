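---
title: "Quantifying mycelial pellet populations: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mycelial pellet populations: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletmorph)
```

## The problem

Filamentous actinomycetes such as *Streptomyces lividans* grow in liquid
culture as mycelial networks that aggregate into anything from dense,
near-spherical pellets to sprawling irregular mats. This morphology strongly
influences growth rate, oxygen transfer and the production of enzymes and
antibiotics, so any attempt to miniaturize a cultivation platform (say, from
a shake flask to 100 µl microtitre wells on a high-speed vortex) must
demonstrate that the *population of particle morphologies* is preserved, not
just the biomass. pelletmorph provides the quantitative machinery for that
demonstration: per-particle morphometry from whole-slide micrographs, a
mixture model describing the heterogeneous population, and calibrated
statistics for deciding whether two conditions are morphologically similar.

## The population model

Submerged *Streptomyces* cultures typically contain two coexisting
subpopulations, one of smaller and one of larger pellets. pelletmorph
models one condition's particles in the plane of maximum Feret diameter
$F$ (µm) and circularity $C$ as a two-component bivariate Gaussian mixture

$$ p(F, C) \;=\; \pi_1\, \mathcal{N}\!\big((F,C)\,;\, \mu_1, \Sigma_1\big)
 \;+\; \pi_2\, \mathcal{N}\!\big((F,C)\,;\, \mu_2, \Sigma_2\big), $$

with full covariance matrices. `fit_bigaussian()` implements the EM
algorithm in-house:

* **Initialization.** The first of `restarts = 10` runs splits the data
  deterministically at the median Feret diameter; the remaining runs draw
  random responsibilities. The best final log-likelihood wins. The
  deterministic first start makes the default fit reproducible, the random
  restarts protect against poor local optima.
* **Convergence.** A run stops when the log-likelihood improves by less
  than `1e-8` or after 500 iterations; the log-likelihood trace is stored
  and is non-decreasing by construction (the test suite asserts this at
  every iteration).
* **Degeneracy.** If a component covariance collapses (determinant below
  `1e-12`), its eigenvalues are floored at `1e-6` and the fit is flagged
  degenerate with a warning.
* **Labelling.** Components are relabelled so that cluster 1 always has
  the smaller mean Feret diameter (the "small pellet" population). The
  participation factor PF1 is 100 × the mixing weight of cluster 1.
* **Covariance structure.** Full covariance per component, because pellet
  size and shape are correlated within a subpopulation; features are fitted
  on their raw scales (µm, unitless), matching how the population plane is
  usually plotted. Z-scoring is used only when ranking particles by
  distance to a cluster centroid (`representative_particles()`), where the
  two axes must contribute comparably.
* **Seeding.** The default seed is fixed at 1400 so that repeated runs of
  the same analysis agree; every seed is an explicit, overridable argument.

Per-cluster 95% confidence intervals use the plain large-sample formula
$1.96\, s/\sqrt{n}$ (`confidence_interval()`), with the sample standard
deviation on the $n-1$ denominator. By default they are
responsibility-weighted (weighted sd, effective cluster size
$n = \sum_i r_{ik}$): the weighted cluster mean coincides with the
mixture mean, so the printed interval always brackets the printed µ.
Computing them instead on hard-assigned members (`weighted_ci = FALSE`)
is supported, but when the components overlap appreciably the
hard-member mean drifts away from the mixture mean and the interval can
fail to bracket it — which is why it is not the default.

## The synthetic population generator

`population_spec()` / `sample_population()` invert the population model
into a generator so the entire pipeline can be exercised, and its recovery
properties measured, without microscope data. `reference_population_specs()`
ships the published parameter sets for shake-flask and 800–1800 rpm
micro-culture conditions of *S. lividans*; component standard deviations
are reconstructed from the published CIs with `derive_sd_from_ci()`
($s = \text{halfwidth} \times \sqrt{n}/1.96$), taking each cluster's $n$
as its participation factor times the total count. The per-condition
particle count is not published for the micro-cultures; the default is
n = 500 per condition, matching the approximate shake-flask count, and is
an explicit, flagged assumption.

**Truncation design.** Feret diameters must be positive and circularity
lies in (0, 1], but several published components have standard deviations
of the same order as their means (e.g. 87 µm ± 69 µm for the shake-flask
small-pellet cluster). Three options were considered:

1. *Plain truncation at zero* inflates the realized component mean far
   beyond the nominal value (87 → 101 µm here, a 16% shift), so a
   downstream fit recovers the wrong mean.
2. *Full moment matching* (choosing location and scale of the underlying
   Gaussian so the truncated law has exactly the nominal mean and sd)
   degenerates when sd ≈ mean: the matched location runs to several
   hundred µm below zero and the sampling density becomes near-exponential,
   which a Gaussian mixture no longer describes.
3. *Mean matching* (implemented): the location parameter is re-solved by
   `uniroot()` so the realized mean of the zero-truncated draw equals the
   nominal component mean, while the nominal sd is kept as the Gaussian
   scale parameter. Under strong truncation the realized sd is therefore
   somewhat smaller than nominal.

Mean matching preserves the quantities the population table actually
reports (the cluster means), keeps every sample physically valid, and
degrades gracefully to the identity when truncation is negligible.
`population_moments()` reports the exact realized mean and sd of the
sampling law, and the property tests compare sample moments against those
realized values. Circularity is clipped (censored) to (0, 1]; the induced
point masses at the bounds are part of the realized law and are included
in `population_moments()` via the closed-form censored-normal moments.

The remaining ten features are not given a published joint distribution,
so `default_feature_link()` derives them from the sampled $(F, C)$ by
near-elliptical geometry — e.g. area $= \tfrac{\pi}{4} F^2 q$ with axis
ratio $q$ tied to circularity, perimeter back-computed so that
$C = 4\pi A / P^2$ holds before noise — times multiplicative lognormal
noise (sdlog 0.08, 0.02 for the perimeter). The links are monotone, so
feature *ranks* are preserved: a bigger, rounder particle in the
generative plane stays bigger and rounder in every derived feature. This
emulates realistic cross-feature correlation structure; it does **not**
emulate measurement artefacts of real micrographs (focus gradients,
overlapping particles, debris), so tests passing on synthetic tables
validate the statistical machinery, not the microscope.

## The synthetic micrograph renderer

`render_image()` turns an `image_spec()` into a grayscale image, a label
mask, and a ground-truth table. "Pellet"-class objects are ellipses whose
axis ratio is solved numerically so the smooth outline realizes the target
circularity, drawn solid to 90% of their radius with a linear intensity
ramp to 110% (the ramp mimics the fringe of peripheral hyphae and gives
the thresholder a realistic soft edge). "Mat"-class objects are branched
2D random walks (branching probability 0.2 per step, reflected at the
target radius) dilated by a 2 px disc — purely a fixture, not a growth
model. Objects may not overlap and must lie fully inside the canvas unless
edge clipping is explicitly allowed; violations name the offending object.
Rendering is bit-reproducible for a fixed spec. Round-trip accuracy
(render → segment → measure) is about 2–5% on Feret and well within 0.15
on circularity for the pellet class; mats have no round-trip guarantee.

## Imaging estimators

`measure_particles()` computes twelve features per labelled particle. The
estimator choices that matter:

* **Perimeter** uses the Moore-neighbour boundary chain code with
  corner-corrected weights (0.980 per straight step, 1.406 per diagonal,
  −0.091 per direction change), plus a half-pixel outward offset (+π)
  because the pixel-centre polygon runs half a pixel inside the true
  boundary. On a rasterized disk of radius 50 px this lands within 0.5%
  of $2\pi r$; a plain (1, √2) chain code would be ~5% high and push disk
  circularity down to ~0.9.
* **Circularity** $4\pi A/P^2$ is hard-capped at 1.0: for very small
  rasterized disks any perimeter estimator can overshoot slightly.
  Consequently the invariant "perimeter ≥ perimeter of the equal-area
  circle" holds by construction after the cap.
* **Feret diameters** are measured on the convex hull of the boundary
  pixels' *corner* cloud (each boundary pixel contributes its four
  footprint corners): max Feret as the hull diameter, min Feret by
  rotating calipers over hull edges. Using corners rather than centres
  removes the systematic 1 px underestimate — a 100 × 50 px rectangle
  measures min Feret exactly 50.
* **Moment ellipse** from second-order central moments with the 1/12
  per-pixel footprint correction; its perimeter by Ramanujan's second
  approximation.
* **Box-counting dimensions** use dyadic box sizes from 2 px to a quarter
  of the bounding box and a least-squares slope in log–log space,
  requiring at least four sizes (objects ≥ 64 px across), otherwise the
  feature is NA. The box *mass* dimension uses the sandbox variant
  (pixel mass inside boxes grown around the centroid — exactly 2.0 for a
  filled disk); the box *surface* dimension counts grid boxes meeting the
  boundary. Both are clamped to the theoretically admissible [1, 2].
  Finite-range box counting is biased slightly low on ideal fractals: the
  quadric Koch fixture of theoretical dimension 1.5 measures ≈ 1.43.
* **Coordinates** are 0-based with pixel centres at integer positions;
  objects touching the image border are excluded by default since partial
  particles bias Feret statistics.
* **Perimeter ratio** is implemented as convex-hull perimeter divided by
  particle perimeter (≤ 1, lower for branched outlines); this
  interpretation is isolated in one function should a different definition
  be preferred. Mean/SD are grey-level statistics over the particle's
  pixels.

Segmentation (`segment_particles()`) is deliberately standard — optional
median-filter despeckle, Otsu or fixed threshold, 8-connected labelling,
area and border filters — and delegates those primitives to EBImage.

## Similarity statistics

`similarity_profile()` runs, for each of the twelve features, a Tukey HSD
over *all* conditions in the data set (the full family of pairwise
comparisons, as the studentized-range calibration assumes) and reports the
accept flag of the (test, reference) pair; the profile total (0–12) counts
"significantly similar" features. `pc_similarity()` does the same on PC1
and PC2 scores after projecting every condition into the PCA space fitted
on the reference condition only (`fit_pca()`, `pca_project()`); the
reference model is never refit, so all conditions are compared in the
directions where the reference varies most — empirically PC1 collects the
size features and PC2 the shape features.

Design choices and caveats:

* "Similar" is operationalized as *failure to reject* at family-wise error
  0.05: the Tukey interval for the pair contains zero. This is the only
  reading consistent with reporting intervals plus an accept flag, but
  absence of evidence of difference is not evidence of equivalence — with
  small samples everything is "similar". For a positive claim,
  `tukey_hsd(..., equivalence_margin = delta)` provides a TOST-style
  criterion (interval inside ±δ); it is off by default.
* Features are standardized before PCA by default (they mix µm², µm and
  unitless scales; without standardization the area variance dominates).
  The choice is recorded in the pipeline log.
* Studentized-range quantiles come from `stats::qtukey`; unequal group
  sizes use the Tukey–Kramer adjustment. The implementation is verified
  against `stats::TukeyHSD` and against a longhand example using published
  critical-value tables.
* The twelve per-feature outcomes are *not* additionally corrected across
  features: the profile total is a raw count of per-feature decisions.

Under the null (two conditions drawn from one population spec, n = 500
each) the per-feature acceptance probability is 0.95, so profile totals of
11–12 dominate, and both-PC acceptance sits at 0.95² ≈ 0.90 — the test
suite measures both.

## Assays

Two spectrophotometric readouts accompany platform comparisons:
`tyrosinase_rate()` (OLS slope of A475 over time for L-DOPA conversion,
with an optional max-R² linear-window detector that is logged when used)
and `actinorhodin_concentration()` (Beer–Lambert at 542 nm with
ε = 18600 L mol⁻¹ cm⁻¹). Both are linear in the dilution factor, which is
always a user input: the chloroform–methanol extraction implies a
phase-volume correction that cannot be inferred from the absorbance, so it
is never guessed.

## Problem sizes and reproducibility

The validation suite uses the sizes a desk check affords: recovery
simulations with 500 particles × 20 seeds per condition, Tukey calibration
with 7 × 500 observations × 1000 replicates, null-similarity with 50
replicate pairs. Every stochastic step takes an explicit seed, the
pipeline writes a configuration hash into each output file, and rerunning
`run_pipeline()` with the same configuration reproduces every output file
byte for byte.

## Known limitations

* The mixture is fixed at two components; no model selection over the
  number of clusters is attempted.
* The generator emulates population statistics, not optics: no PSF, focus
  variation, or particle overlap, and hyphal growth is not simulated.
* The EM fits an *unbounded* Gaussian mixture to data that are truncated
  and clipped by physical bounds; with components as dispersed as some
  published ones, recovered small-cluster means carry a few percent of
  downward bias (documented in the tests' tolerances).
* Fractal dimensions need objects at least 64 px across; calibrate the
  optics (pixel size) accordingly.
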