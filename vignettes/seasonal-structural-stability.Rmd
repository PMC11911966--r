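---
title: "Seasonal structural stability: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal structural stability: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasonstruct)
```

## The scientific problem

Diverse tree communities often produce more wood than the average of their
component monocultures — the net biodiversity effect (NBE), or
overyielding. One proposed mechanism is that species with different
architectures and phenological rhythms fill canopy space in complementary
ways **through time**: a community whose three-dimensional structure stays
stable across the growing season is, on this view, one whose members
partition light capture across the year. `seasonstruct` provides the
machinery to quantify that idea in a tree diversity experiment surveyed
repeatedly by UAV-LiDAR: per-survey structural metrics, their seasonal
stability, ground-based productivity and its diversity partition, multiple
dimensions of diversity and variability, and the statistical models that
tie them together.

Because the package must be verifiable without access to any particular
field campaign, it also contains a synthetic forest-scene generator whose
outputs exercise every stage of the pipeline with known ground truth.

## Structural metrics

Three metrics are computed per plot and survey, after conditioning
(below):

**Canopy height heterogeneity** `HH_cv` is the coefficient of variation of
a 0.1 m-resolution digital canopy model (cell-wise maximum normalized
height). Empty cells are *excluded*, not zero-filled: zero-filling would
conflate canopy gaps with height variance, and the two are ecologically
distinct. The sample (n − 1) standard deviation is used here and in every
other CV in the package; the alternative population convention changes
values by a factor √((n−1)/n) and none of the qualitative conclusions.

**Fractional cover** `FC` divides the sum of inverse return numbers of
vegetation returns (height > 0.25 m) by the number of pulses. A
first-return interception counts fully, a second return counts half, and
so on; pulses are identified by `return_number == 1` when pulse ids are
absent. The estimator can in principle exceed 1 when a pulse yields
several vegetation returns and no ground return; such values are clamped
to 1 with a warning.

**Fractal dimension** `d_D` generalizes box counting with Hill diversity.
For voxel edge sizes *S* from 0.1 to 2.25 m (twelve log-spaced values —
the range is a property of plot-scale clouds, and log spacing balances
leverage in the log–log fit), points are assigned to voxels anchored at
the cloud's minimum corner, and the occupancy proportions give
`qD = (Σ pᵢ^q)^(1/(1−q))`. `d_D` is the standardized-major-axis slope of
`log D` against `log(1/S)`. The default order q = 0.999 approximates the
information dimension while damping point-density differences between
plots; within 10⁻⁶ of q = 1 the Shannon limit `exp(−Σ p log p)` is used.
SMA rather than ordinary least squares because neither axis is an error-free
predictor; the slope is `sign(r)·sd(y)/sd(x)`.

Two practical caveats, verified empirically in the tests: box counting on a
*bounded* uniform solid is biased at coarse scales (partial voxels inflate
the coarse-end diversity), so a 3 m cube recovers d ≈ 2.88 on scales
0.1–1.5 m but only ≈ 2.8 on the full default range; and occupancy
saturates when the voxel count approaches the point count. Planes and
lines recover 2.0 and 1.0 within 0.15 on the default scales at 10⁵
points.

**Stability.** For each metric, seasonal structural stability is the
inverse coefficient of variation `SS = x̄/σ` over the season's surveys
(eight by default). SS is scale-invariant and requires a complete series;
a zero-variance series returns `Inf` flagged `perfectly_stable` (this
occurs in the synthetic world when a dense evergreen canopy saturates
FC at 1 at every survey; such plots drop out of the model fits, which
filter to finite values). Plots enter seasonal analyses only if their
maximum canopy height exceeds 1.5 m at *every* survey, their mean planting
year predates 2019, and they were not replanted during the productivity
interval.

## Point-cloud conditioning

The chain is normalize → clip → SOR → decimate.

* *Normalization*: the ground surface is the per-cell minimum on a 1 m
  grid, bilinearly interpolated between cell centres; z becomes height
  above that surface, and points at or below 0.25 m are classified ground.
  This grid-minimum method is appropriate for the flat or gently sloping
  terrain of a designed experiment (residuals < 0.1 m on a 2 % synthetic
  slope); it is not a general-purpose ground classifier.
* *Clipping*: points strictly inside the plot polygon shrunk by 0.5 m are
  retained (a point exactly on the buffered boundary is excluded). On a
  10 m square this leaves the 81 m² analysis region that matches the
  ground-based interior. Only convex polygons are supported — inward
  offsetting is then exact via half-plane intersection.
* *SOR*: for each vegetation point (z > 0.25 m), the mean distance to its
  30 nearest vegetation neighbours; points above the 97.5 % quantile
  (type-7, linear interpolation — stated so the threshold is reproducible)
  of that distribution are removed. Points at or below 0.25 m pass through
  untouched. The distance statistic is the *mean* neighbour distance;
  the filter is deliberately not idempotent (a second pass recomputes the
  quantile on the filtered cloud and trims again), which is inherent to
  quantile-based outlier removal.
* *Decimation*: one point per occupied 1 cm voxel, first-in-input-order
  wins. The grid is anchored at the cloud's minimum corner snapped down to
  the absolute voxel lattice; with a raw minimum-corner anchor, removing
  points would shift the grid and re-bucket survivors, so decimation would
  not be idempotent. Both box counting and decimation are origin-sensitive,
  which is why the anchors are documented and fixed.

## Ground-based quantities

Stem volume uses solids of revolution: a conoid
`V = H·π·D_rc²/12` up to 1.3 m, and above that a conoid frustum from root
collar to breast height plus a conoid to the tip,
`V = 1.3·(D_rc² + DBH·D_rc + DBH²)·π/12 + (H−1.3)·π·DBH²/12`. Both agree
with numerical quadrature of the corresponding radius profiles to 10⁻⁹
relative. Dead trees contribute zero volume in the year of death, so
mortality enters productivity as a negative increment. Annual wood
productivity divides the volume change by the inter-inventory interval
(days / 365) and the 0.0081 ha interior plot area; the outer 0.5 m ring of
trees is excluded throughout.

`NBE = AWP_plot − Σᵢ AWPᵢ pᵢ` with *planted* proportions and per-species
monoculture means taken as the grand mean over monocultures planted before
2019 and not replanted (block-specific means are a documented alternative;
the grand mean is used because monoculture replicates per block are
scarce). The Loreau–Hector partition uses the population (divide-by-n)
covariance so that `CE + SE = NBE` holds exactly, to 10⁻⁹ over 1,000
random plots in the tests. Species with zero monoculture yield are
excluded with a warning rather than producing infinite relative yields.

## Diversity and variability

Richness, phylogenetic diversity and functional diversity are Hill-number
quantities at q = 0. PD is the branch-length sum of the union of
root-to-tip paths of the community — the stem to the root is included, so
a single species carries its full root-to-tip depth. FD is the *ordered*-pair
sum of Euclidean distances on z-scored traits (twice the unordered
sum); traits are standardized because their units are incommensurable. The
dendrogram-based alternative (branch lengths of the functional tree) can
be obtained by passing the functional dendrogram to `phylo_diversity`.

Variability is the Helmus phylogenetic species variability,
`PSV = (n·tr C − ΣC)/(n(n−1))` with C the correlation matrix implied by
shared branch lengths — computed by subsetting the full-tree covariance so
root-shared history is preserved (pruning first would discard it). It is 1
on star trees at any richness, invariant to branch-length rescaling, and
undefined for monocultures. The same machinery runs on three tree types:
the phylogeny, a UPGMA dendrogram of trait distances (UPGMA because the
metric requires ultrametric trees), and a UPGMA tree of unit-step
taxonomic distances (1 = congeners, 2 = confamilials, 3 = same order,
4 = beyond; equal steps, matching the equal-step convention of vegan's
`taxa2dist`, against which the tests cross-check).

## The statistical layer

Cross-sectional regressions are ordinary least squares per survey day;
volumes, diversities and stability metrics are natural-log transformed
(they are strictly positive and right-skewed), NBE never is (it can be
negative). Mixed models use `response ~ predictor × DOY + (1 | block/plot)`
with DOY continuous and centred; a singular nested fit falls back to a
plot-only random intercept with a warning. Significance is two-sided at
0.05 with no multiple-testing correction, reported per model.

The SEM is estimated by maximum likelihood in a RAM parameterization
written for this package: latent Diversity and Variability (variances
fixed at 1, correlation free) each measured by three indicators; SS
regressed on both latents; NBE on SS, Variability and (by default,
configurable) a direct Diversity path. Variables are standardized and
incomplete or non-finite rows dropped listwise; the discrepancy
`log|Σ(θ)| + tr(SΣ⁻¹) − log|S| − p` is minimized by BFGS from a fixed
start (loadings 0.7, paths 0, residual variances 0.5, latent correlation
0.3), standard errors come from the numerical Hessian, and standardized
coefficients use model-implied variances. Perfectly collinear indicators
raise an identification error (singular sample covariance);
non-convergence is flagged and warned, never silent. On simulated tables
with a known Variability → SS → NBE chain the fitter recovers signs and
approximate magnitudes at n = 150, and under a null generator R²(NBE)
stays below 0.1 in ≥ 90 % of seeds.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions of the package:
12 species (4 evergreen) on an ultrametric phylogeny whose deepest split
separates the leaf habits; traits 70 % Brownian along the tree, 30 %
independent noise, mapped to realistic ranges (wood density ~0.5 g cm⁻³,
LMA higher in evergreens, heights 15–35 m at maturity); three blocks;
monocultures of every species plus mixtures at richness 2–12 with equal
planted proportions; 100 trees per plot on a 1 m grid with the outer ring
excluded (the 81 m² interior); planting years 2016–2018 with a 5 %
replanting flag; 5 %/yr mortality; eight surveys at DOY 100, 138, 163,
188, 215, 250, 261, 297; 100 pulses m⁻² (decimation makes the metrics
insensitive to density beyond this); 0.1 % sky-noise outliers 2–10 m
above the canopy. Per-species phenology dates (flush DOY 112–135,
senescence 270–292, sharpness 5–9 days) are free parameters of a
double-sigmoid curve — no field campaign's species are being estimated.
Where a value had no stated counterpart, it was chosen once on
plausibility grounds and not revisited.

Crowns are cones (evergreen) or ellipsoids (deciduous) whose union is
sampled by vertical (nadir) pulses on a jittered grid — oblique scan
geometry is not modelled because the metrics depend on return and height
structure, not scan angle. Interception follows a Beer–Lambert-style
probability `1 − exp(−k·L·φ)` with path length L, extinction k = 0.8 m⁻¹
and foliage fraction φ from the phenology curve; a deciduous crown retains
a woody fraction (0.15) when leafless, as real leaf-off LiDAR sees
branches. Lower interceptions register only if the pulse survived the
crowns above it, and at most two vegetation returns are kept per pulse
(the emulated sensor records up to three returns including ground); the
ground return appears with probability `exp(−τ)` of the total optical
depth, and always when nothing intercepted. Without the survival thinning,
multi-return weighting drives FC above 1 — an estimator, not a generator,
artifact that the thinning removes at its physical source.

The injected diversity effect multiplies year-2 growth by
`1 + complementarity × functional variability` of the plot (zero for
monocultures). Because the effect is *relative*, absolute NBE is
confounded with baseline productivity (NBE ≈ multiplier × expected AWP);
recovery checks therefore correlate the injected score with relative
overyielding `NBE/AWP_expected`, and the end-to-end tests hold planting
year constant to remove the age confounder. What passing these tests shows
is that the pipeline *recovers what the generator encodes* — phenology
asynchrony, crown-volume filling, complementarity-dominated overyielding.
What it cannot show is anything about real forests: no wind, no waveform
radiometry, no calibrated allometry, no interannual climate, and trait
effects on growth far simpler than nature's.

## Problem sizes and numerical choices

The test suite runs the full chain on reduced studies (6–12 species, 4–8
survey days, 40–100 pulses m⁻², ~30–50 plots), sizes chosen so the whole
suite completes in a few minutes while every stage and invariant is
exercised; the acceptance script uses 10⁵-point geometry fixtures, 150-plot
SEM tables with a 20-seed null, and 20 evergreen/deciduous monoculture
pairs over the eight survey days. RNG streams are derived by hashing the
master seed with plot id and survey day, so any single plot-survey can be
regenerated in isolation and all results are exactly reproducible given
one integer. Ties in decimation resolve to input order; quantiles are
type-7 everywhere; SMA fits with zero response variance return a flagged
zero slope (a uniform box-count curve), and degenerate canopies (mean
height 0, or a single occupied cell) raise errors rather than returning
numbers.

## Known limitations

The ground model assumes near-flat terrain. FC saturation can make
perfectly stable evergreen plots drop out of log-scale analyses. The
SS_dD/SS_FC versus SS_HHcv contrast in strength of association with NBE is
not statistically resolvable at the synthetic scales used here (two dozen
mixtures), so the tests assert only the robust parts of the qualitative
pattern: overyielding, complementarity dominance, and a positive
SS_FC–relative-overyielding association. The SEM fitter covers exactly the
model family described above; it is not a general SEM engine.
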