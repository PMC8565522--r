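---
title: "Connectivity-based callosal topography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based callosal topography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cctopo)
```

## The problem

The corpus callosum (CC) carries nearly all direct interhemispheric
traffic, but it is not homogeneous: fibres serving visual cortex cross in
the splenium, motor fibres in the body, prefrontal fibres in the genu.
`cctopo` partitions the CC by *where streamlines of each functional
network cross it*, then asks how the microstructure of each
network-specific subregion changes across the adult lifespan. Real
tractography cohorts are rarely shareable, so the package pairs the
analysis code with a synthetic generator that reproduces the statistical
structure the analysis assumes; everything below applies identically to
real inputs (TCK tractograms, NIfTI label volumes and diffusion maps in a
common space).

## From streamlines to connection maps

A streamline is accepted for network *n* when (a) both endpoints fall in
label-*n* voxels of the cortical label volume, (b) the endpoints lie in
opposite hemispheres, and (c) its voxel path intersects the callosal mask.
We read "connecting a functional network" as *homotopic*: both endpoints
in the same network. Heterotopic streamlines (different networks at the
two ends) are dropped and tallied in the QC log, because the per-voxel
normalisation `P(s,v,n) = FN(s,v,n)/Σₙ FN(s,v,n)` presumes each
streamline contributes to exactly one network. Hemisphere membership is
the sign of world *x*, with the midsagittal plane at *x* = 0 — the
anatomical definition of left/right for a midline structure.

Endpoint membership is tested on the cortical labels dilated by a 2 mm
Euclidean ball (anisotropic voxels respected), the conventional margin for
catching streamlines that terminate just short of the grey–white boundary.
Where dilations collide, the voxel goes to the nearer original label, with
exact-distance ties resolved to the lower label index so the result is
deterministic.

Voxel traversal densifies each streamline to a point spacing of half the
smallest voxel dimension, maps points to the nearest voxel centre
(voxel-centred convention, 0-based indices), and deduplicates per
streamline — a voxel visited twice by one streamline counts once, so
`FN(s,v,n)` counts *streamlines*, not visits. One numerical caveat is
worth stating: point-sampled traversal can skip a voxel whose chord
through the rounding cell is shorter than the sampling step. Against an
exact analytic traversal (splitting each segment at every rounding-cell
boundary), the sampled path is always a subset; on pathological random
oblique polylines it misses ~10–15% of grazed corner voxels, while on
bundle-like, near-axis-aligned streamlines the miss rate is negligible.
The tests assert the subset property and coverage rather than a spurious
exact equality between two sampling resolutions.

## Population atlas, hard segmentation, reproducibility

The atlas is the voxel-wise arithmetic mean `P(v,n) = (1/S)ΣₛP(s,v,n)`;
the hard segmentation takes the arg-max over networks, ties to the lowest
index, zero-probability voxels left unlabelled. Reproducibility is
assessed by splitting the cohort into two age- and sex-matched halves:
subjects are stratified on (age bin × sex), each stratum is shuffled and
divided as evenly as possible, and odd subjects alternate between halves
(singleton strata are pooled into that alternation, with a warning). The
two halves' hard segmentations are compared with per-label Dice
`2|Aₗ∩Bₗ|/(|Aₗ|+|Bₗ|)`. Because a single summary number over
multiple labels is not uniquely defined, the report carries per-label
values plus two reductions — unweighted and size-weighted means — and uses
the size-weighted mean as the headline figure, the closest single-number
analogue of an overall overlap.

## Subregional metrics

Subregional connection probability divides by the *template* callosal
voxel count `V` (fixed per phantom or template mask), not by each
subject's support: `P(s,n) = ΣᵥP(s,v,n)/V`. Summed over networks this
equals (support voxels)/V ≤ 1, which is the intended behaviour — sparse
maps yield lower subregional probabilities.

Probability-weighted diffusion indices use, by default, the *population*
atlas channel as the weight image (`weight_source = "population"`), i.e.
the population topography evaluated in the subject's space; a config
switch selects each subject's own map instead. Voxels with FA at or below
0.2 are excluded — the standard partial-volume guard against grey matter
and CSF — and the FA gate comes from the subject's FA volume for *all*
four indices, including MD/RD/AD, so all indices are extracted over one
voxel set. If no voxel survives, the value is flagged missing with a
warning rather than an error, and downstream fits drop it pairwise.

Nuisance covariates (TIV in cm³, sex coded 0/1, education in years,
entered linearly) are regressed out by OLS with the grand mean restored,
so residualised values stay on the original scale; the operation is
mean-preserving and idempotent, and a rank-deficient covariate matrix is
rejected with the collinear columns named. Age is deliberately *not*
among these regressors when the residuals feed the trajectory fit; the
between-subregion comparison, by contrast, residualises age out too,
since there age is a nuisance.

## The quadratic trajectory model

`fit_quadratic()` fits `DI = C + A·age + B·age²` by least squares.
Internally ages are centred before solving and the coefficients mapped
back — the raw design with age² up to 8100 is ill-conditioned enough to
warrant it — but the *reported* parameterisation uses raw age so the
intercepts are directly comparable with conventional tables. Adjusted
R² uses p = 2 regressors (age, age²; the intercept is not counted),
which reproduces published R²/adjusted-R² pairs at n = 1086 to printed
precision. The overall p comes from the regression F statistic and is
reported exactly rather than truncated to "0.000". The turning point is
the analytic extremum `−A/(2B)` — a maximum when B < 0 (FA-style
inverted-U), a minimum when B > 0 (diffusivity-style U) — flagged when it
falls outside the observed age range, absent when B = 0. Note that
turning ages published as figure annotations do not always match
`−A/(2B)` computed from the accompanying coefficient tables (the default
FA rows give ≈43.6 y for the DA subregion and ≈48.3 y for VIS); the
package always reports the analytic value implied by the coefficients.
Degenerate inputs — fewer than 4 usable subjects, or fewer than 3 distinct
ages — raise an error in the single fit and a "failed" row (run
continues) in the per-cell table.

## Group statistics

The age-group comparison of `P(s,n)` is an ordinary linear model with
group dummies plus sex, education and TIV — mathematically the ANCOVA —
with the omnibus F from the nested-model comparison and pairwise contrasts
as adjusted-mean differences with pooled-error t tests, Bonferroni-corrected
over m = g(g−1)/2 pairs at α = 0.05. Raw values enter the model (the
covariates adjust within it; residualising first would be equivalent).
Between-subregion comparisons of the diffusion indices use paired t tests
on residualised values with Bonferroni m = K(K−1)/2 — a deliberate
simplification of full repeated-measures ANOVA machinery (no sphericity
correction), documented as such.

## What the synthetic generator emulates — and what it does not

The phantom is a 2 mm isotropic grid (13 × 39 × 9 voxels for K = 7,
13 × 91 × 9 for K = 17) holding a 3-voxel-thick midsagittal callosal slab
of 297 template voxels, K disjoint 27-voxel crossing zones ordered
anterior → posterior, and one homotopic pair of lateral cortical boxes per
network. Bundles are quadratic Bézier arcs whose crossing points cycle
deterministically through every zone column, so at zero jitter a bundle
covers its zone exactly and the hard segmentation equals the generative
zones voxel for voxel. Defaults, chosen once as plausible study
conditions: 60 streamlines per network, endpoint jitter 1 mm (half a
voxel — endpoint dispersion of probabilistic tracking), crossing-point
jitter half that, 10% distractor streamlines (same-hemisphere arcs or
endpoints outside any label, which the assignment rules must reject).

Cohorts draw integer ages either uniformly on 21–90 or in "table1" mode
reproducing the reference seven-bin composition (73, 41, 42, 413, 305,
188, 24 at n = 1086); education declines and TIV shrinks mildly with age,
sex is balanced. Diffusion volumes fill each zone with the generative
quadratic plus a *subject-level* deviation shared across the zone's voxels
(between-subject variability, calibrated per row so a refit recovers the
published R²: `σ² = Var[f(age)]·(1−R²)/R²` over the age grid) plus
smaller voxel-level noise (default σ/4). Covariate effects apply to
centred covariates (TIV − 1400 cm³, education − 10 y, sex − 0.5) so the
trajectory intercepts remain cohort means; they default to zero because
published effect sizes are not available, and exist to exercise the
residualisation machinery. Non-zone callosal voxels receive a
deterministic quota of sub-threshold FA (default 50%) to exercise the FA
gate, and zero-noise volumes are bit-identical whatever the seed. For
K = 17 the seven coefficient rows are recycled cyclically across
subnetworks, as no published 17-network coefficient table exists.

The generator does *not* emulate: curved three-dimensional callosal
geometry, registration error between spaces, heterotopic connections,
distance-dependent streamline seeding density, spatially correlated noise,
or any coupling between connection probability and the diffusion indices.
Passing tests therefore validate the *pipeline arithmetic and statistical
calibration*, not robustness to registration artefacts or biological
confounds in real data.

## Problem sizes and determinism

The shipped analyses use 1086-subject scalar cohorts for trajectory
recovery, a 200-subject phantom cohort (100 per split half) for
reproducibility, 10⁵ subjects for the noise-calibration consistency
check, and 2000 null replicates (70 subjects each) for the type-I-error
calibration of the omnibus test. One user seed fans out to per-stage seeds
as `(seed·1009 + k) mod (2³¹−1)`, so stages are independently
re-runnable and identical configurations give byte-identical tabular
outputs.

## Known limitations

- The hard segmentation inherits arg-max instability where two networks'
  probabilities nearly tie; Dice between cohort halves is the designed
  check for how much this matters at a given sample size.
- Paired-contrast subregion comparisons understate within-subject
  correlation structure relative to full RM-ANOVA.
- The generative model treats the four indices as independent given age;
  real FA/MD/RD/AD are strongly coupled.
- With the population atlas as weight image, subjects contribute to their
  own weights through the atlas mean; at the shipped cohort sizes the
  leakage is O(1/S) and immaterial, but single-subject "atlases" should
  use subject weights.
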