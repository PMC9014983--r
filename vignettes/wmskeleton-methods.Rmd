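---
title: "Skeletonized white-matter statistics: models, inference and the synthetic cohort"
author: "wmskeleton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeletonized white-matter statistics: models, inference and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmskeleton)
```

# The problem

Diffusion-MRI studies of aging summarize white-matter microstructure by
scalar maps — fractional anisotropy (FA), mean/radial/axial diffusivity —
projected onto a tract skeleton common to all subjects (the TBSS
approach). The scientific questions this package serves are of the form:

* Is a behavioral score (here, working-memory accuracy under different
  cognitive loads) associated with the metric at each skeleton voxel,
  after adjusting for age and sex, and is that association independent of
  processing speed?
* Does the metric **mediate** the age difference in the behavioral score,
  voxel by voxel?
* Do genotype groups (e.g. dopamine-related polymorphisms) differ in the
  metric, and does that difference grow with age?

All three are voxelwise questions over tens of thousands of correlated
tests, so the package pairs every map with threshold-free cluster
enhancement (TFCE) and max-statistic permutation inference for
family-wise error (FWE) control.

# Data model

Four S4 classes carry the data:

* `SkeletonSpace` — the voxel grid, its 4x4 voxel-to-world affine, the
  skeleton mask (stored as sorted linear indices, which fixes the
  voxel-to-column bijection), and optional integer tract labels.
* `MetricStack` — a subjects x skeleton-voxels matrix of one scalar
  metric. FA values are validated to lie in [0, 1] and no undefined
  values may occur inside the mask; values outside the mask are never
  materialized.
* `StatMap` — one value per skeleton column with a statistic kind
  (`t`, `z`, `tfce`, `p`, `mean`) and a direction tag.
* `PermutationResult` / `MediationResult` — inference outputs bundling
  observed maps, the null sample of per-permutation maxima, and
  FWE-corrected p-maps.

Masks, stacks (4D, subject last) and stat maps read and write NIfTI via
RNifti; tract labels travel as an integer volume plus a JSON name table.
DTI scalars can be recomputed from tensor eigenvalues with
`dtiScalars()`; the FA of an all-zero tensor is defined as 0 (the
convention of the standard FSL tooling), with a warning.

# Voxelwise GLM

`fitVoxelwiseGLM()` fits ordinary least squares at every voxel and
returns the t-statistic of a user contrast with residual df $n - p$. The
implementation is a single set of matrix products across voxels, and is
tested against a per-voxel `lm()` oracle to $10^{-8}$ relative
tolerance. Contrasts are directional ("greater" or "less"): the paper
domain reports one-sided findings (positive metric-behavior
associations, negative age effects), so maps for each direction are
computed separately and tagged. Convenience wrappers build the
condition-pair slope comparison (both condition scores standardized so
their slopes are commensurable, contrast $(1, -1)$) and indicator-coded
genotype or age-split group contrasts, including the group-by-stratum
product term for interaction tests. Missing behavioral values are
handled by listwise deletion per model.

# TFCE

For a nonnegative map $m$, the enhanced value at voxel $v$ is

$$\mathrm{tfce}(v) \;=\; \sum_{h = dh,\, 2dh,\, \ldots}^{m(v)}
  e(h, v)^{E}\, h^{H}\, dh,$$

where $e(h, v)$ is the size of the connected suprathreshold component
containing $v$ at height $h$, under the configured neighborhood (6, 18
or 26) restricted to the skeleton mask. Defaults are $H = 2$, $E = 1$,
100 steps, 26-connectivity — the convention for skeletonized data;
$E = 0.5$ is offered for volumetric use. Numerical choices:

* $dh = \max(m)/\mathrm{steps}$, with the threshold for step $k$
  computed as $\max(m)\,k/\mathrm{steps}$ so the top step lands exactly
  on the map maximum (no floating-point dropout of the peak);
  suprathreshold comparison uses a $10^{-12}$ relative tolerance.
* Negative values are treated as zero; an all-nonpositive map enhances
  to the zero map rather than erroring.
* Each permuted map in the null loop is enhanced with its own
  map-maximum step height, matching standard practice; a fixed `dh` can
  be supplied when two maps must be compared on a shared threshold grid
  (that is also how the monotonicity property is tested).

The C++ implementation (one component labeling per threshold over a CSR
adjacency of the skeleton graph) is verified exactly against an
independent igraph-based oracle on random 5x5x5 maps, and against the
closed forms $\int_0^{v} h^2\,dh = v^3/3$ for an isolated voxel and
$2\,v^3/3$ for an adjacent pair.

# Permutation inference

`permutationFWE()` uses the Freedman-Lane scheme: residuals from the
reduced (nuisance-only) model are permuted, added back to the reduced
fit, the full model is refitted, and the maximum TFCE-enhanced statistic
over the skeleton is recorded. Nuisance columns are those with zero
contrast weight. The identity permutation is always included as
permutation 1, and

$$p(v) = \frac{\#\{\text{null max} \ge \mathrm{enhanced}(v)\}}{n_{\mathrm{perm}}},$$

with $\ge$ in the counting rule, so the smallest attainable p-value is
$1/n_{\mathrm{perm}}$ (0.0002 at 5,000 permutations). Significance uses
a strict `p < alpha`. Permutation order is deterministic given the
mandatory seed; full enumeration replaces sampling when $n! \le
n_{\mathrm{perm}}$ and `exact = TRUE`. Fewer than 100 permutations is
refused because the null tail is then too coarse to be useful.

Calibration is checked empirically: over 200 null datasets (n = 60, 500
voxels, 300 permutations — sizes chosen to make the check cheap while
leaving the binomial error small), the empirical FWE at nominal 0.05
must lie in [0.025, 0.075].

# Voxelwise mediation

At each voxel of an analysis mask, the indirect effect of age on the
behavioral score through the metric is tested with the Sobel statistic

$$z = \frac{a\,b}{\sqrt{b^2 s_a^2 + a^2 s_b^2 + s_a^2 s_b^2}},$$

where $a$ ($s_a$) is the slope (SE) of the metric on age and $b$
($s_b$) the slope of the score on the metric, controlling age —
estimating $b$ with age in the model is standard Sobel practice, adopted
here as an interpretive decision. Sex (or any covariate set) is first
regressed out of age, score and every voxel's metric; all three are then
standardized so $a$ and $b$ are comparable across voxels. Standard
errors use simple-regression dfs ($n-2$, $n-3$) on the residualized
variables without an extra df correction for the residualization step;
the permutation null, not the nominal normal approximation, carries the
inference. Voxels whose residualized metric is constant are excluded and
counted. The sign of $z$ always equals the sign of $a\,b$; the analysis
enhances the requested sign (default negative: age-related decline
transmitted by the metric) and the analysis mask is typically
`ageEffectMask()` — the FWE-significant voxels of the negative age
contrast.

## Two permutation nulls

The mediation null is composite ($ab = 0$), and no single permutation
scheme is exact for all of it:

* **`"mediator"`** (default): the subject rows of the residualized
  mediator stack are permuted against exposure and outcome, severing
  both mediated links while preserving the exposure-outcome association.
  This is the global "no signal at this voxel" null and the behavior of
  the standard voxelwise-mediation tooling. Within an age-effect mask it
  is anti-conservative at voxels that genuinely carry an age effect but
  no outcome path, because the permutation also destroys the real
  $a$ path.
* **`"outcome"`**: Freedman-Lane permutation of the outcome residuals on
  age, preserving both the age-outcome association and the whole
  $a$ path. This is the calibrated test of the $b$ path at voxels
  already known to show an age effect — exactly the population an
  age-effect mask selects — and it is the scheme the package's
  calibration property uses for that regime (empirical FWE well under
  the 7.5% binomial bound in testing).

Choose the scheme for the null you intend to reject; the default
reproduces the field-standard analysis.

## Change in effect at the peak

`changeInEffect()` quantifies how much of the age effect the peak
mediator absorbs: it fits `score ~ age + sex` and
`score ~ age + sex + metric` and reports both $r^2$, the relative change
$(r^2_{\mathrm{after}} - r^2_{\mathrm{before}})/r^2_{\mathrm{before}}$,
and the age-coefficient t in both models. Because the after-model nests
the before-model, $r^2$ can only increase, while the literature in this
domain speaks of an $r^2$ "drop"; what actually shrinks is age's unique
(squared semipartial) contribution. Both readings are computed and
reported side by side (`relativeChange` vs `ageUniqueChange`), since the
published phrasing does not determine which was meant.

# The synthetic cohort generator

No public data ship with the package; `generateCohort()` and
`generateMetricStack()` produce cohorts with the statistical structure
the analyses assume, so every stage is testable end to end.

What it emulates:

* **Narrow-age-cohort design** — ages drawn from fixed recruitment ages
  (default 25-80 in 5-year steps) with weights skewed toward older
  cohorts, mirroring the demographic table of the study domain;
  a continuous-age analysis needs no change since age enters the models
  as a covariate.
* **Hardy-Weinberg genotypes** at three loci with designated-allele
  frequencies 0.192, 0.562 and 0.471.
* **Working-memory accuracies** out of a ceiling of 18, per condition
  $c$:
  $\mathrm{acc}_c = \mathrm{clip}\big(18 - h_c + s_c\,y_c + h_c e,\,
  0,\, 18\big)$ with
  $y_c = L_c(z - z_{\min}) + b_c(m - a z) + f_c g$, where $z$ is
  standardized age anchored at the youngest cohort, $m = a z +
  \sqrt{1-a^2}\,\varepsilon$ is the latent white-matter integrity
  factor, $g$ a shared ability factor and $e$ Gaussian noise
  (a modeling assumption; the score noise model is not dictated by the
  domain literature). $L_c$ is the **total** standardized age slope
  (defaults $-0.36, -0.23, -0.19$, matched to the published age-group
  means), $s_c$ the score scale in points (2.9, 1.9, 1.4) and $h_c$ the
  residual SD, which doubles as the youngest cohort's headroom below
  the ceiling — so zero slopes with zero noise put every score exactly
  at the ceiling. Scores are continuous and clipped to [0, 18]; integer
  item counts are deliberately not forced, preserving the correlational
  structure. The shared-ability loadings (0.6, 0.8, 0.7) approximate
  the high inter-condition correlations reported in this literature.
* **Planted mediation**: the metric stack gives a `fracEffect` fraction
  of voxels the standardized age slope $a$ (default $-0.4$); a
  `fracMediating` share of those is driven by the same latent integrity
  factor that feeds the scores (path $b$, default 0.3 for the
  highest-load condition, load-graded 1/0.8/0.5 across conditions),
  mixed with voxel noise at weight 0.15. Latent factors are
  orthonormalized **in-sample**, so the planted standardized paths hold
  for the drawn sample up to the voxel-noise attenuation
  ($\sqrt{1-0.15^2} \approx 0.989$); parameter-recovery tests therefore
  measure estimator bias, not draw-to-draw sampling noise.
* **Planted geometry**: mediating voxels occupy the first skeleton
  columns and age-only voxels the last ones, so each truth class is a
  connected cluster but the two classes are disconnected. TFCE
  integrates extent across connected voxels by design; placing the two
  classes adjacent would let the mediating cluster's enhancement chain
  into the age-only block and make voxel-level truth labels
  unevaluable.
* **Exclusions and outliers**: staged exclusion flags with first-stage
  attribution and an exactly conserving ledger; the bivariate 3.5-SD
  outlier rule with mean and SD computed once on the input (a constant
  variable removes nothing, with a warning).

What it does **not** emulate: registration or skeleton-projection error,
spatially autocorrelated voxel noise, crossing-fiber geometry,
age-dependent (heteroscedastic) score noise, integer item scores, or any
anatomy in the affine (synthetic spaces use a 1 mm identity affine and
box-shaped skeletons). Passing tests therefore demonstrate that the
estimators and the inference machinery behave as specified under the
assumed generative model — not that any particular anatomical claim
about real cohorts is reproduced.

Sex is coded 0 = female, 1 = male and induces no effect unless
configured. A single master seed drives every stage through
deterministically derived sub-seeds, so a cohort, its exclusions and its
metric stack are jointly reproducible.

# Pipeline

`runPipeline()` sequences the full replica — cohort (simulated or
loaded), exclusions, per-condition metric-score GLMs with age and sex,
the same models with processing speed added, condition-pair load
contrasts, the age-effect mask, mediation, genotype and
age-by-genotype contrasts, and the summary reports (Hardy-Weinberg
statistics, slice profiles, tract coverage, demographic tests). Subjects
missing a behavioral score are dropped per model, not globally. Outputs
are NIfTI maps, TSV tables and a JSON manifest whose content is
byte-identical across reruns of the same config and seed (wall-times go
to a separate log). The age-split boundary for the interaction analysis
defaults to 60 years and is configurable. A thin command-line front end
(`inst/scripts/wmskeleton.R`) exposes the stages as subcommands.

# Problem sizes and tolerances

The test suite and the acceptance script run the stochastic checks at
these sizes, chosen as the package's own operating points: FWE
calibration on 200 null datasets of n = 60 subjects, 500 voxels and 300
permutations (nominal 0.05, accepted band [0.025, 0.075]); mediation
recovery on one cohort of n = 200, 2,000 voxels and 500 permutations
(at least 80% of mediating voxels FWE-significant, at most 5% of
non-mediating voxels, planted paths recovered within 0.05 on average);
the permutation floor at 5,000 permutations on a 500-voxel skeleton.
TFCE oracle equivalence is exact to floating-point round-off; the
single-voxel closed form is met within 2% at 200 integration steps.

# Known limitations

* The Sobel test is a normal-theory approximation used here only as a
  map statistic; no bootstrap mediation intervals, multiple mediators,
  or longitudinal/causal mediation are provided, and cross-sectional
  mediation supports no causal claim.
* TFCE parameters are conventions, not estimates; results can shift
  with H, E and connectivity, which is why they are explicit,
  validated parameters logged in every run manifest.
* The permutation engine targets single contrasts; no variance
  smoothing or cluster-extent alternatives are implemented.
* The generator's exact in-sample planting makes recovery tests sharp
  but means its "population" parameters are sample-anchored; simulation
  studies of sampling variability should re-draw cohorts rather than
  reuse one.
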