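---
title: "Mapping highly biodiverse areas with oceub: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping highly biodiverse areas with oceub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reserve-selection methods usually presume that we know where species live.
In megadiverse tropical regions that premise fails: occurrence records are
sparse, spatially biased toward accessible places, and cover taxa unevenly,
so a map of "observed biodiversity" is to a worrying degree a map of
collecting activity. `oceub` implements a spatially explicit prioritization
chain that (i) builds several complementary biodiversity surfaces on a
one-degree hexagonal grid while actively correcting for effort, (ii)
stratifies the study area into biogeographic regions of unique species and
lineage composition so that irreplaceable biotas are never traded against
each other, (iii) searches, with a genetic algorithm, for the weighted
combination of surfaces and the selection threshold that captures the most
biodiversity in the least area, and (iv) reports, instead of hiding, where
the data are too thin to say anything (cells of insufficient information).

## The model chain and its assumptions

### Grid and records

All analyses happen on flat-topped hexagons whose across-flats width is the
cell size (default 1 degree) laid out in geographic coordinates. Hexagons
are the Voronoi cells of their centers, so point-to-cell assignment is a
nearest-center search, with ties going to the lower cell id. Records are
never silently dropped: rows with unparseable or out-of-range coordinates
are kept with `valid_geo = FALSE`, and geographic validation against a
caller-supplied boundary polygon only flips that flag. Duplicate records
are retained deliberately — they carry information about sampling effort,
and the richness resampling neutralizes their effect on richness.

### Biodiversity surfaces

*Weighted endemism (WE).* Each species contributes the inverse of its
distribution area, operationalized as its occupied-cell count, to every
cell it occupies. Summed over the grid this returns exactly the number of
species, a conservation identity the test suite asserts on arbitrary
fixtures.

*Phylogenetic weighted endemism (PWE).* The same idea lifted to branches:
each branch of the (unit-branch-length) tree contributes its length divided
by the number of cells in which it occurs. Branch occurrence areas are
counted in cells, not km², to stay commensurate with the analysis grid.
The grid-wide sum equals the total branch length represented in the data.

*Resampled species richness.* Counting species per cell confounds richness
with effort. Instead, every cell is surveyed with the same simulated
effort: per repetition, 50 records are drawn with replacement from the
cell's records and a 25% subsample (floor: 12 records) is drawn without
replacement from them; the number of distinct species in the subsample is
averaged over 1,000 repetitions. Cells with fewer than 50 records are
bootstrapped rather than excluded (exclusion would empty most cells of any
sparsely sampled dataset); cells with zero records are no-data. The
marginal distribution of the subsample equals 12 independent draws from the
cell's empirical species distribution, which yields the closed form the
tests check against and makes the estimate invariant to duplicating every
record.

*Areas of endemism (GIE).* Species are classed into nine groups by the
distance from their range centroid to their farthest record (upper edges
50, 200, 400, 600, 800, 1000, 1500, 2000, 3299 km; larger distances fall
into class 9 with a warning). Per class, an Epanechnikov kernel density of
the class's centroids is computed with radius equal to the class edge;
class surfaces are summed with weight 1/edge — narrow-ranged species
dominate by construction — and the consensus is rescaled to [0, 1]. The
source method leaves kernel and weighting open; this combination is a
documented choice validated by planted-hotspot recovery rather than by
literal fidelity to any particular implementation.

*Interpolation.* All quantitative surfaces except areas of endemism are
interpolated to every grid cell by ordinary kriging: an empirical
semivariogram (12 lags to 60% of the maximum distance), a weighted-least-
squares fit of an exponential model, and an exact solve of the ordinary-
kriging system at each cell center. Parameter uncertainty is propagated in
the empirical-Bayesian spirit by re-estimating the variogram on random 80%
subsets (20 by default) and averaging the resulting predictions; their
spread is reported alongside. With a zero nugget the interpolator is exact
at sample locations. Kriging is planar over the grid's extent; at
subcontinental scales the distortion is well below the variogram
uncertainty.

### Regionalization

Cell-by-cell Sorensen and PhyloSor dissimilarities (the latter computed
from shared branch length of root-inclusive minimal subtrees, so it reduces
exactly to Sorensen on a star tree) are ordinated by non-metric
multidimensional scaling — Kruskal stress-1, isotonic regression, random
restarts with the metric solution as the first start — and each ordination
axis is kriged to the full grid. Only cells with at least 5 records enter
the dissimilarity stage; composition "estimated" from a singleton is noise,
and kriging fills the gaps exactly as it does for the other variables. The
default dimensionality is 3 for both the species and the phylogenetic
ordination (kept low because the downstream classifier works on the joint
axis vector), and 100 restarts is the desk-scale default with the option
of running thousands.

The stacked composition surfaces are classified by a Gaussian
maximum-likelihood classifier fitted unsupervised (an EM Gaussian mixture;
each cell gets its maximum-posterior component). The number of regions is
chosen by BIC over 2–12 unless fixed by the caller. Exactly duplicated
surfaces are dropped before fitting, which makes the partition invariant to
duplication and avoids singular covariances. Labels are canonicalized by
descending region size. No spatial smoothing of labels is applied by
default; a majority filter over hex neighbours is available behind a flag.

### Optimization

Within each region, every surface is rescaled to [0, 1] (biotas of
different regions are irreplaceable and must not compete on raw scale). A
candidate solution — the genome — is five numbers in [0, 1]: weights for
richness, endemism, areas of endemism and phylogenetic endemism, plus a
quantization threshold. The weighted sum is rescaled to [0, 1] globally
(so the threshold allele means the same thing for every weight vector) and
cells at or above the threshold are selected. The fitness of a selection is

```
(r + pl + e + pe) / 4  -  a / A
```

where `r` is the fraction of species with at least one selected occupied
cell, `pl` the captured fraction of total branch length, `e` the captured
fraction of total endemism weight (a species' full WE counts once any of
its cells is selected), `pe` the same at branch level, `a` the number of
selected cells and `A` the total cell count. Selecting everything scores
exactly 0; capturing everything in a vanishing area approaches 1. A
`cellsum` capture mode (fractions as sums of surface values over selected
cells) is available behind an option for sensitivity analysis; the
species-level reading is the default because the endemism index is defined
per species.

The genetic algorithm is elitist: population 20, up to 100 generations,
the all-0.5 "primeval" genome seeding the initial population, top 25%
kept, a further 15% random survivors for diversity, uniform crossover
(rate 0.9), clipped Gaussian mutation (per-allele rate 0.2, sd 0.1), and a
15-generation stall stop. The best-so-far individual is never lost, so the
best-fitness history is nondecreasing, and the whole run is a pure
function of the seed. The operator rates are not prescribed by any
external source; they are package defaults, all exposed in `gaConfig()`.

### Sampling effort and categories

Sampling effort is the quartic-kernel density of all geographically valid
records, reported as expected records per cell; the bandwidth is the
spatial variant of Silverman's rule of thumb,
`0.9 * min(SD, sqrt(1/ln 2) * Dm) * n^(-0.2)` (SD the standard distance,
Dm the median distance to the mean center), with one cell width as the
fallback when all points coincide. Cells below a cutoff — by default the
median of the positive-effort distribution, overridable as an absolute
density — are insufficiently sampled, and insufficiency overrides
relevance: no cell is ever reported (non-)relevant where the data cannot
support the claim. A vegetation mask, when supplied, is stamped as a
sub-flag without changing the main category.

## The synthetic landscape

Because the real multi-million-record databases behind analyses of this
kind are not shippable, the package carries a generator that plants the
exact structure the chain assumes: three vertical-band regions with fully
distinct species pools (each species' disc range is clipped to its own
region, so cross-region Sorensen dissimilarity is exactly 1); 50 species
per region of which 30% overall are narrow-ranged endemics co-centered on
one compact hotspot (radii 0.3–0.9 degrees, i.e. the two smallest
range-size classes) while the remaining species are widespread within
their region (radii 4–8 degrees — each region is an internally homogeneous
unique biota, which is precisely the premise regionalization rests on); a
phylogeny with one clade per regional pool (so phylogenetic composition
carries the regional signal) and unit branch lengths; and a smooth
south-to-north accessibility gradient, deliberately orthogonal to the
east-west regional structure so effort artifacts are identifiable against
the planted biology. Sampling is species-first (species weighted by range
area, a cell uniform within the range, a point uniform within the cell)
with optional effort-proportional thinning (`bias` exponent).

What the generator does *not* emulate: niche-driven range shapes,
taxonomic error, spatial error in coordinates, abundance structure within
cells, and range-size distributions with realistic skew. Tests passing on
this landscape show the chain recovers planted structure under its own
assumptions; they do not certify performance on real, messier data.

The reference study conditions used by the end-to-end tests are the
generator defaults (18 x 10 degree extent at 1 degree, 3 regions, 150
species, 20,000 records) with landscape seed 3 and pipeline seed 1; they
run the full chain in about two minutes on one CPU. At these conditions
the optimized model captures over 90% of species and of endemism weight in
a few percent of the cells, recovers the planted hotspot core completely,
and regionalization recovers the planted bands with an adjusted Rand index
above 0.8.

## Numerical choices and degenerate inputs

- Ties in point-to-cell assignment (a record exactly on a shared edge) go
  to the lower cell id; points on a boundary polygon edge count as inside.
- A constant region under within-region rescaling becomes all zeros with a
  warning; an all-zero weight vector yields an all-zero relevance surface
  with a warning; no-data cells are never selected by thresholding.
- Kriging falls back to a ridge-regularized solve if the system is
  singular and jitters exactly duplicated sample locations; constant
  samples short-circuit to a constant surface.
- NMDS collapses zero-dissimilarity duplicates before fitting and assigns
  them identical coordinates afterwards; an all-zero dissimilarity matrix
  is an error, not a silent degenerate fit.
- The richness subsample size is `floor(n_per_sample * fraction)` — a
  deterministic round-down (12 for the defaults).
- Distances beyond the last range-size class edge (3,299 km) are classed 9
  with a warning rather than erroring.
- Effective sample sizes in the correlation screen are clamped to [3, n].

## Known limitations

- The effort-decorrelation advantage of resampled over naive richness is
  small at desk scale (correlation differences of a few hundredths) and
  can be masked on landscapes whose true richness pattern happens to
  correlate with the effort field; the reference landscape keeps the two
  orthogonal by construction.
- The EM classifier sees cells as exchangeable observations; spatial
  autocorrelation of the composition surfaces can make BIC prefer more
  components than planted regions (sub-structure such as the hotspot's
  distinct composition is genuinely there, but a user wanting exactly the
  planted coarse regions should fix `k`).
- Kriging is planar and the variogram isotropic; strongly anisotropic
  gradients would need a generalization.
- MRP supertree search is a heuristic (random addition + NNI restarts);
  exhaustive certainty is only feasible, and only used in tests, for tiny
  taxon sets.
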