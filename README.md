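# contactniche

Comparative analysis of ecological niche expression across species contact
zones. The package is written for spatial ecologists studying pairs of
closely related, parapatric species that meet in narrow zones of sympatry,
and who want to ask: do the two species segregate their niches where they
co-occur, does landscape disturbance shift the balance between a generalist
and a specialist, and do niche models fitted in one contact zone say
anything useful about another?

It provides, as one tested workflow:

- **KDE hypervolume niches** in principal-component space: Gaussian
  product-kernel density estimates with per-axis Silverman bandwidths
  `b_j = sd_j (4 / ((d + 2) n))^(1/(d+4))`, thresholded to retain 95% of
  the KDE's probability mass, with the region volume estimated by
  importance sampling from the KDE itself.
- **Niche overlap indices** from volumes `V1`, `V2` and their intersection
  `I`: the Sørensen index `K = 2I / (V1 + V2)` and the overlap index
  `OI = I / min(V1, V2)` (the observed overlap relative to the maximum the
  smaller niche allows — preferred when niches differ in size), with
  permutation randomisation tests that re-split the pooled scores and
  rebuild both hypervolumes per permutation.
- **Competition-aware ensemble niche models**: presence / pseudo-absence
  logistic regressions in which pseudo-absences are drawn inside the
  *competitor's* range (minimum convex polygon), encoding biotic exclusion;
  30 replicates with fresh pseudo-absences and stratified 80/20 splits, the
  10 best by test TSS (`sensitivity + specificity − 1`) averaged into a
  probability map, with coefficient-based variable importance and response
  curves.
- **Transferability scoring** of models projected to other areas: TSS on
  the target records, MESS extrapolation surfaces (per-variable similarity
  to the training domain; negative = novel conditions) and Miller's
  calibration regression of observations on the logit of the predictions
  (intercept 0, slope 1 = calibrated).
- **Sympatry mapping**: fuzzy (min) intersection of two species'
  probability maps and co-occurrence profiles along a transect placed
  orthogonally to the contact.
- A **synthetic landscape generator** (smooth correlated climate fields,
  softmax landcover fractions, a disturbance scalar that homogenises
  habitat, Gaussian niche truths for a generalist, a specialist and an
  allopatric third species) so the entire workflow is testable against
  known answers.

## Worked example

Simulate a landscape with the default study design (a 190 × 190 km area
with three contrasting contact zones), draw occurrences for the generalist
and the specialist, and compare their climatic niches:

```r
library(contactniche)

cfg   <- study_config(seed = 42)
stack <- generate_environment(cfg$landscape)
clim  <- paste0("clim", 1:9)
pca   <- fit_pca(rs_values(stack, clim))

occA <- simulate_occurrences(stack, cfg$truths$aspis,    300, seed = 1)
occB <- simulate_occurrences(stack, cfg$truths$latastei, 300, seed = 2)
hvA  <- build_hypervolume(project_scores(pca,
          rs_extract(stack, occA[, c("x", "y")], clim)), seed = 3)
hvB  <- build_hypervolume(project_scores(pca,
          rs_extract(stack, occB[, c("x", "y")], clim)), seed = 4)
pairwise_overlap(hvA, hvB)
```

```
<overlap_result> V1 85.64, V2 42.02, I 35.31 | K 0.553, OI 0.840
```

The generalist's climatic hypervolume (`V1 = 85.6`) is about twice the
specialist's (`V2 = 42.0`), recovering the 2× per-axis breadth built into
the truths. `K = 0.553` says the intersection is a bit over half the mean
niche size; `OI = 0.840` says the specialist's niche lies mostly inside
the generalist's — the asymmetry `OI > K` is exactly why OI is reported
alongside K when niches differ in size.

`run_study(study_config(seed = ...))` executes the full design — two
ordinations, a 26-row overlap table (zone environmental variability, each
species across zones, species × species per area, with permutation
p-values), the 24-ensemble factorial (2 species × 3 variable sets × 4
areas), the cross-area transfer matrix and per-zone sympatry profiles —
and `write_study_report()` saves the tables, occurrences and run manifest.

## Notes

- Rasters are handled by a lightweight in-package grid container (named
  matrices plus origin/cell size) with ESRI ASCII grid and CSV
  input/output; coordinates are planar km on a 1-km lattice.
- All stochastic steps take explicit seeds, and multi-stage runs derive
  per-stage seeds from one master seed (`child_seed()`), so every result
  is reproducible bit-for-bit.
- The methods vignette (`vignettes/contact-zone-workflow.Rmd`) documents
  the estimators, their assumptions, the synthetic-data design and known
  limitations.
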