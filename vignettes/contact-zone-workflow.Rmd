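---
title: "Methods: niche overlap, ensemble models and sympatry across contact zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche overlap, ensemble models and sympatry across contact zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `contactniche`: what
each estimator assumes, which tunable parameters matter, how the synthetic
landscape generator is designed, and where numerical choices were made that
a careful user should know about.

## The scientific setting

Two closely related, parapatric species meet in narrow contact zones whose
abiotic conditions differ from one zone to the next. Three questions
structure the workflow: (1) how do the zones differ environmentally, and
how much of each species' niche is expressed locally in each zone; (2)
which climatic and landcover variables drive each species' distribution in
each area, once interspecific competition is encoded in the modelling
design; and (3) where does co-occurrence concentrate spatially. The
package answers these with, respectively, kernel-density hypervolumes and
overlap indices, ensembles of competition-aware logistic niche models, and
fuzzy co-occurrence maps summarised along transects.

## Ordination

Climatic and landcover variability are summarised by two separate PCAs
(`fit_pca()`), fitted on the **cells of the large study area** and on the
correlation matrix (variables standardised), because environmental
variables mix units (temperature, precipitation, fraction cover). All
occurrences and zone backgrounds are *projected* into this one space
(`project_scores()`), never re-ordinated per area: volumes and
intersections are only comparable across areas if they live in the same
coordinates. Loading signs are fixed (largest-magnitude entry positive) so
the decomposition is deterministic. The first `k = 3` components are used
for hypervolumes; three axes retain the bulk of structured variance in
both spaces while keeping Monte-Carlo volume estimation well-conditioned —
beyond about five dimensions the estimator degrades and the package does
not support it.

## Hypervolume niches

A species' niche in score space is the region where a Gaussian
product-kernel KDE of its occurrence scores exceeds a density threshold
(`build_hypervolume()`):

1. per-axis Silverman bandwidths
   `b_j = sd_j * (4 / ((d + 2) n))^(1/(d+4))`;
2. `n_mc` samples drawn *from the KDE itself* (pick a point, add kernel
   noise), default `n_mc = 10000 d`;
3. the threshold is the `1 - quantile` quantile (default mass
   `quantile = 0.95`) of the KDE density evaluated at those samples, so
   ~95% of the KDE's probability mass lies inside the region. The
   "quantile threshold" is deliberately interpreted as **probability-mass
   retention**, because that interpretation has an analytic Gaussian
   benchmark (below);
4. the volume is the importance estimate
   `V = mean over retained samples of 1/f * fraction retained`, an
   unbiased estimate of the Lebesgue measure of the super-level set;
5. `n_uniform` representative points (default 1000) are resampled from
   the retained samples with weights `1/f`, giving a uniform sample of
   the region used for intersection estimates.

**Assumptions and behaviour.** The KDE convolves the data with the kernel,
so the hypervolume of an `n`-point Gaussian sample is inflated by roughly
`(1 + b^2)^(d/2)` relative to the underlying distribution's own 95%
highest-density ellipsoid; at `n = 5000` in 3-D this is ~12%, partly
offset by the roughness of the finite mixture. The package's acceptance
benchmark (volume of a trivariate standard normal sample vs the analytic
ball `V = (4/3) * pi * (chi2_{3,0.95})^{3/2} = 91.5`) sits near the edge of
a 10% band for exactly this reason; the benchmark is run at
`n_mc = 100000` to make the Monte-Carlo component of the error negligible
against this systematic term. Volumes are comparable *between* species and
areas at similar `n`, which is how they are used.

**Overlap.** `pairwise_overlap()` estimates the intersection symmetrically
from each region's uniform points:
`I = (V1 * frac(points of 1 in 2) + V2 * frac(points of 2 in 1)) / 2`,
clipping (with a warning) the rare Monte-Carlo excursions above
`min(V1, V2)`. The indices are `K = 2I/(V1+V2)` and `OI = I/min(V1,V2)`;
`OI >= K` always, and `OI` is the right summary when a small niche sits
inside a large one. `OI` is implemented as `I/min(V1, V2)` — equivalently
`K` divided by its maximum attainable value given the two volumes — which
reproduces published index tables from their printed volume triples to
rounding precision.

**Permutation tests** (`permutation_overlap_test()`) pool the two score
sets, re-split them at the observed sizes, and rebuild *both* hypervolumes
per permutation — bandwidths re-estimated per split, since the null
hypothesis is exchangeability of the scores, not of the fitted densities.
The default p-value is one-sided for segregation
(`p = (1 + #[null <= obs]) / (n_perm + 1)`, default `n_perm = 100`)
because the biological hypothesis is *less* overlap than random; a
two-sided variant is available. Environmental-variability comparisons
reuse the same machinery on uniform subsamples of each zone's cells
(default 2000 cells, seeded).

## Ensemble niche models

`fit_ensemble()` fits presence / pseudo-absence logistic regressions where
the biotic context enters through the pseudo-absence design: absences are
drawn uniformly from cells inside the **competitor's minimum convex
polygon** (and a third, allopatric species' range where configured),
excluding only the modelled species' exact presence cells. Cells in the
sympatric overlap are *eligible* — excluding them would erase the
competitive signal the design is meant to encode. The pseudo-absence count
equals the presence count in every replicate.

Per replicate (default 30): fresh pseudo-absences, a fresh stratified
80/20 split, a logistic fit by IRLS with a tiny ridge (`1e-6`) that keeps
coefficients finite under complete separation (a warning is raised), and
TSS on the held-out 20%. The 10 best replicates by test TSS are kept —
TSS is the design's only performance metric, so "best" means highest test
TSS — and averaged into the probability map; the per-cell sd across kept
replicates is retained as a stability diagnostic. Predictors are
standardised with the *training area's cell statistics* so coefficients
are comparable across variables and replicates; variable importance is
the kept-replicate mean (± sd) of these standardised coefficients, flagged
at `|mean| >= 0.5` by default. Models are linear in the standardised
predictors by default; quadratic terms are available
(`quadratic = TRUE`) for unimodal responses, at the cost of
less-interpretable coefficients.

Response curves (`response_curve()`) bin the training-area cells by a
variable's observed value (25 equal-width bins) and average the ensemble
probability per bin — empty bins are reported as missing, not zero — with
a partial-dependence variant (other predictors held at the training mean)
behind a flag.

## Transfer scoring

`project_ensemble()` applies the kept replicates to a target area using
the **source** standardisation statistics: transfer asks how the fitted
response performs under the target's absolute conditions, so the target is
never re-standardised. `evaluate_transfer()` scores the projection with
TSS against target records and same-rule pseudo-absences, the MESS
extrapolation surface, and Miller's calibration regression.

MESS (`mess()`) uses the training-area *cells* (the model domain, not just
presences) as the reference sample; per variable, with `f` the percentage
of reference values below the point: `f = 0` maps to
`100 (p - min)/(max - min)`, `0 < f <= 50` to `2f`, `50 < f < 100` to
`2(100 - f)`, `f = 100` to `100 (max - p)/(max - min)`; the score is the
minimum across variables, so adding a variable can only lower it, and
negative values flag novel conditions.

Miller's calibration is the logistic regression of observations on the
logit of predictions (clipped to `[1e-6, 1 - 1e-6]`); (0, 1) means
calibrated. Under this recalibration convention, systematic
*over*-prediction yields a **negative** intercept, while overestimation is
often verbally reported with the opposite sign; because the two
conventions coexist in the literature, the sign-flipped intercept is also
returned (`intercept_overestimation`, positive = overprediction) and users
should state which they report.

## Sympatry mapping

`fuzzy_intersection()` combines two species' probability maps with the
fuzzy AND — `min` by default, the standard fuzzy-overlay intersection;
`product` is available since both are defensible, and `min` is the more
conservative upper bound on co-occurrence. `auto_transect()` takes the
cells above the 0.9 co-occurrence quantile, reads the contact's average
direction from their first principal axis, and runs the transect through
their centroid along the *second* axis, extended to the zone boundary; a
near-isotropic cell cloud (axis-length ratio > 0.95) triggers a warning
and an x-axis tie-break, and user-supplied endpoints always bypass
detection. `transect_profile()` projects every cell centre orthogonally
onto the segment, *excluding* (not clamping) cells whose foot falls
beyond the endpoints, because profiles are read along a finite transect.

## The synthetic landscape generator

Real occurrence and environmental data for this kind of study are rarely
redistributable, so the generator is a first-class module: every
downstream estimator is exercised against known truths.

What it emulates, and the defaults chosen as the study conditions:

- a 190 × 190 km planar grid at 1 km resolution, holding three 35 × 35 km
  contact zones that differ in climate through a north–south gradient
  (0.02 and −0.015 units/km on the first two climate axes) and in
  landscape disturbance (0 "natural", 0.8 "intensive agriculture",
  0.4 "abandoned fields");
- nine climate layers: smooth Gaussian random fields (white noise
  convolved with a Gaussian kernel, autocorrelation length 8 cells, unit
  marginal variance) optionally mixed to a target correlation matrix,
  plus the gradient and per-zone offsets;
- four landcover fractions from a softmax over latent smooth fields (plus
  a residual class, so fractions sum to ≤ 1); disturbance `d` mixes each
  cell's composition convexly towards a dominant-agriculture profile,
  which provably raises the agriculture fraction cellwise and lowers
  Shannon evenness;
- Gaussian niche truths over four climate axes (generalist sd 1.6, twice
  the specialist's 0.8) and two habitat axes with *class-specific*
  preferences (the generalist centred on forest, the specialist on
  shrub; sd 0.25 vs 0.125). The climate niches span several variables so
  the breadth asymmetry survives ordination; the habitat optima are
  separated by more than the generalist's own habitat breadth so that
  habitat segregation can register in `OI` where the landscape is
  heterogeneous — a 2×-broader niche on a *shared* axis simply contains
  the specialist's and forces `OI ~ 1` everywhere;
- record counts fixed at 421/450 for the two focal species over the large
  area (52/60, 133/95, 50/50 inside the zones) and 135 records of an
  allopatric third species (29 in the northern zone), used only as a
  pseudo-absence source; one record per 1-km cell, at cell centres.

What it does **not** emulate: observation bias (records are sampled
exactly proportionally to occupancy; an optional bias field would be a
straightforward extension but no default bias is claimed), temporal
structure, dispersal limitation, or real geodesy (coordinates are planar
km). Passing the recovery tests therefore shows the estimators recover
truths under ideal sampling, not that any field dataset satisfies these
conditions.

## Numerical choices and problem sizes

- All stochastic steps take explicit seeds; multi-stage runs derive child
  seeds as a hash of (master seed, stage label, replicate index), so
  stages are reproducible independently and uncorrelated.
- TSS threshold ties break towards the lower threshold; kept-replicate
  ties break by replicate order.
- Intersection estimates are clipped to `min(V1, V2)` with a warning;
  density evaluations drop kernel contributions beyond 120 squared
  bandwidth units (relative error < 1e-25).
- Degenerate inputs error early and explicitly: zero-variance axes
  (bandwidths, PCA standardisation), fewer than `d + 1` points, fewer
  than 3 non-collinear points for a hull (unless a buffer is supplied),
  constant predictions in Miller's regression, degenerate MESS reference
  ranges.
- The test suite runs the full study design at reduced Monte-Carlo
  resolution (e.g. `n_mc` 1500–6000, 150–300 representative points, 99
  permutations in the calibration study, 20 seeds for the recovery
  study); these sizes are resolution choices that leave the study
  conditions — record counts, niche truths, ensemble replication 30/10 —
  at their defaults.

## Known limitations

- Volume estimation is supported up to ~5 dimensions; the Monte-Carlo
  estimator's variance grows quickly beyond that.
- The KDE bandwidth convolution inflates absolute volumes at small `n`
  (see the benchmark discussion above); comparisons between hypervolumes
  built at very different sample sizes inherit this bias differentially.
- `OI` of a small niche inside a large one saturates at 1 by
  construction; pair it with `K` and the raw volumes when reporting.
- The permutation null re-splits pooled scores, which conditions on the
  combined sample; with strongly unequal sample sizes the test's power is
  driven by the smaller group.
- Pseudo-absence sampling requires enough eligible cells inside the
  competitor's range; extremely clumped competitor records in a small
  zone can make the design infeasible, which the package reports as an
  explicit error rather than silently relaxing the rule.
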