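---
title: "Methods: distance-based regionalisation with a cluster coherence index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based regionalisation with a cluster coherence index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelfprov)
```

# The analysis

`shelfprov` regionalises gridded occurrence data in five stages: record
quality control, equal-area gridding with per-rank incidence matrices,
pairwise Simpson turnover, hierarchical clustering with an objective
cut-off rule and coherence scoring, and temperature-coupling analyses.
This vignette explains each model and the choices behind it, in the order
a run executes them.

## Record quality control

Occurrence-database extracts carry characteristic defects: fossil records
flagged as modern, missing or out-of-range coordinates, records placed
exactly on the prime meridian or equator (a classic georeferencing
artefact), kilometre-scale coordinate uncertainty, pre-1900 collection
dates, pelagic taxa in a benthic compilation, points on land, and records
from beyond the shelf. `apply_filters()` removes these in a fixed order —
cheap attribute checks first, spatial checks last — and attributes every
removed record to the *first* failing filter, so the removal counts add up
to the input count exactly.

Two policies are deliberately permissive: records with *missing*
uncertainty or *missing* year are retained, because only stated violations
(uncertainty above 100 km, year before 1900) are evidence of a problem,
and dropping missings would silently discard a large share of legitimate
museum records. Both policies are switchable in `qc_config()`.

The land test works against an elevation raster (negative below sea
level): a record passes if its nearest raster sample is below sea level or
if any below-sea-level sample lies within a 0.1° buffer of it. The buffer
is expressed in degrees, not metres, because shoreline records with
imprecise coordinates scatter in coordinate space; its effective reach is
bounded below by the raster's sample spacing, so the bathymetry raster
should be at least as fine as the buffer (the synthetic world uses 0.05°
samples against the 0.1° buffer).

The depth rule is applied twice: at the record level where a depth value
is present (depth > 200 m removes the record), and at the cell level
during gridding (`shallow_cell_mask()` keeps every cell containing at
least one raster sample in the (0, 200] m depth band). The *presence* rule
— any shallow sample admits the cell — is used rather than a cell-mean
rule, because shelf cells are routinely part deep ocean, and a mean rule
would discard exactly the narrow-shelf cells the analysis cares about.

Taxonomic harmonisation is a table contract (`harmonize_taxonomy()`):
the caller supplies a synonymy exported from a taxonomic backbone, names
are replaced by their accepted equivalents, and records whose status is
nomen nudum, nomen dubium, taxon inquirendum, uncertain, or non-marine are
removed. No live service is queried, which keeps runs reproducible.

## The equal-area grid

The grid is a cylindrical equal-area (Behrmann, standard parallel 30°)
tessellation with square cells (default edge 250 km, a standard grain for
global marine macroecology). The projection is implemented from the
closed-form spherical formulas at radius 6371.0088 km (the IUGG mean
radius), which makes the equal-area property exact by construction. Grid
lines are anchored at the projection's natural origin and cells are
half-open intervals `[x0, x1) × [y0, y1)`, so boundary points have a
deterministic owner. The grid's column direction is periodic in longitude;
because the world's width is generally not an integer number of cells, the
two partial columns flanking the antimeridian are treated as adjacent for
neighbourhood purposes.

Incidence matrices are built per systematic rank. Records identified at a
lower rank roll up through the taxonomy (a species record is evidence for
its genus and family); records identified above the target rank are
unusable at that rank and are ignored. Presence is a union, so repeated
evidence is idempotent.

## Simpson turnover and cell exclusions

Compositional difference between cells is measured by the Simpson
dissimilarity, the turnover component of the Sørensen index:
`min(b, c) / (a + min(b, c))`. The nestedness component is deliberately
disregarded: cells differ enormously in sampling effort, and a
richness-sensitive index would measure effort, not biogeography. The value
is 0 whenever one cell's taxa nest inside the other's, and 1 for disjoint
cells; empty cells are undefined and excluded with a log entry.

Before ordination, two exclusion rules apply (`exclude_cells()`): cells
with fewer than 10 records (too little evidence for a composition), then
cells whose row-mean dissimilarity exceeds 0.99 or falls below 0.01
(extreme outliers that are usually data errors). The record-count rule
belongs to the ordination path only; the clustering path retains all
non-empty cells, since average linkage is robust to sparse cells and the
coherence index flags the damage they do. The mean-dissimilarity rule runs
after the record-count rule; both stages are logged separately.

## Clustering, the cut-off rule, and coherence

Both UPGMA (size-weighted average linkage) and WPGMA (simple average) are
fitted; the tree whose cophenetic distances correlate better with the
original matrix wins (ties fall to UPGMA, flagged). The linkage engine is
`stats::hclust`; its merge heights are verified in the test suite against
a naive O(n³) re-implementation, exactly, on hundreds of random matrices.

Cut-off levels are chosen by rule, not by eye: the upper threshold is the
largest merge height at which at least `min_large_clusters` (default 10)
clusters of at least `min_size` (default 5) cells remain; the lower
threshold is the smallest at which at least 95 % of cells belong to such
large clusters; levels are spaced at 0.04 distance intervals, anchored at
the lower threshold and stepped upward (anchoring at the lower bound is
the convention fixed here; the constraint curves for both thresholds are
returned for inspection, and an empty feasible range is an error carrying
them). Clusters below `min_size` are "grey": kept in the labels, excluded
from summaries, coherence scoring and inter-cluster matrices.

Each large cluster is then scored with the Cluster Coherence Index

$$I_{CC} = \sqrt{\frac{\bar d + \bar d\,(1 - \hat N)}{e\,\sqrt{c}}}$$

with `c` the cell count, `d̄` the mean pairwise haversine distance among
cell centroids (WGS84 longitude/latitude, radius 6371.0088 km), `e` the
cell edge length, and `N̂` the fraction of cells with a same-cluster cell
among their 8 queen neighbours. Distance alone would penalise elongate
coastal clusters; neighbourhood alone could not see the width of gaps.
The combination is scale invariant (rescaling `d̄` and `e` jointly leaves
it unchanged) and penalises full disjunction by exactly √2 relative to
full contiguity. Values at most 1 are coherent, above 1 indicate outliers,
above 2 an incoherent cluster; boundary values fall in the lower class
because both escalations are strict inequalities.

Three conventions are fixed and configurable where meaningful: the focal
cell does not count as its own neighbour (otherwise `N̂ ≡ 1`); a singleton
cluster has `d̄ = 0` and hence index 0 (it has no pairs — and it is grey
anyway); and neighbourhoods wrap across the antimeridian in the column
direction but not across the poles in the row direction. Grid-index
adjacency, not great-circle adjacency, defines the 3 × 3 neighbourhood —
the difference only matters in the highest-latitude rows, which shelf
analyses rarely populate. `cell_size_robustness()` re-renders a cluster
shape at a series of cell sizes; the index profile is flat to within a few
percent across the 10–2000 km range and only degenerates when cells stop
fitting on the sphere.

## Ordination and temperature coupling

The dissimilarity matrices go into non-metric multidimensional scaling
(`vegan::monoMDS`, global model, Kruskal stress-1). "100 iterations" of
the classical protocol is read as 100 restarts of the majorisation scheme:
one metric (principal-coordinates) start plus 99 random configurations,
each refined to tolerance 1e-7 with at most 500 inner iterations, keeping
the lowest-stress solution. Dimensions default to 2/3/4 for
species/genus/family — coarser ranks have more diffuse structure and need
more room. Scores are then rotated to principal axes, sign-fixed so the
largest-magnitude score on each axis is positive (this makes the output
invariant to rotations and reflections of the input configuration, which
are arbitrary in nMDS), and min-max scaled to [0, 1]; a zero-variance axis
is pinned at 0.5 and flagged. The radial colour coding (hue from the angle
about the centroid, saturation from the square root of relative radius,
extra axes darkening the value channel) exists for visual comparison of
maps and ordinations; nothing quantitative depends on it.

Per-cell temperature is the temporal mean of the monthly SST rasters,
averaged first over months and then over the raster samples inside each
cell. The coupling is quantified two ways. A Gaussian GAM fits SST as a
single penalised thin-plate smooth of all ordination axes, with smoothing
chosen by GCV; adjusted R² and deviance explained are reported, and the
default basis dimension (30) shrinks with a flag when few cells are
available. And a permutation Mantel test correlates the condensed
taxonomic and temperature (Euclidean) distance vectors, permuting one
matrix's labels jointly; the test is one-sided ("greater") with
`p = (1 + #{r_perm ≥ r_obs}) / (n_perm + 1)` and 999 permutations by
default, so a negative association reports p near 1 and the smallest
achievable p is 0.001. The suite verifies type-I error calibration
(rejection rate at α = 0.05 within [0.03, 0.07] over 500 null replicates)
and uniformity of null p-values.

## The synthetic world

Because no fixed reference dataset ships with the package, validation runs
against a generator (`build_world()` / `sample_occurrences()`) that
reproduces the statistical structure the analysis assumes:

* a shelf strip hugging a meridional coastline, `coast_width_cells` wide
  (default 5), with provinces stacked as latitudinal bands of
  `cells_per_province` cells in serpentine order. A one-cell-wide strip
  cannot hold realistic province counts (a 250-km column only fits ~58
  cells pole to pole), so the strip is a few cells wide; each province
  still occupies a distinct latitude band with its own mean SST;
* a linear latitudinal SST gradient (default 0.45 °C per degree latitude
  from 28 °C at the equator, with a ±2 °C seasonal cycle whose annual mean
  is exactly the base field);
* nested taxa: species group into genera across neighbouring provinces
  and genera into families, so thermal envelope and geographic range widen
  with rank (niche s.d. defaults 1/5/15 °C for species/genus/family);
* occupancy by thermal filtering: a species occupies a cell of its
  province with probability given by a Gaussian kernel of the cell SST
  around its optimum, truncated at the province boundary except for rare
  leak events (`turnover_sharpness`, default 0.02);
* negative-binomial per-cell record counts (mean 50, size 5), mimicking
  the heavy geographic unevenness of real databases, with 90/7/3 % of
  records identified to species/genus/family rank;
* optional defect injection at configured rates, at most one defect per
  record, with hidden truth labels so filter fidelity can be audited
  exactly.

All randomness flows from one master seed through labelled sub-streams
(`derive_seed()`), so worlds, occurrence tables and full pipeline runs are
byte-identical across replications.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data — includes: realistic coastline
geometry and fragmented shelves, ocean-current structure and the east–west
barriers it creates, temporal SST dynamics beyond a fixed seasonal cycle,
taxonomic error (misidentification, synonym drift), and spatially
correlated sampling artefacts. The generator establishes that the
machinery recovers planted structure under the stated statistical
assumptions; it cannot establish that real faunas satisfy those
assumptions.

## Validation conditions and problem sizes

The end-to-end checks run under fixed study conditions chosen once: a
6-province × 40-cell world with 80 species per province,
`turnover_sharpness` 0.02 and ~50 records per cell for province recovery
(adjusted Rand index ≥ 0.9 at some selected cut-off, all recovered large
clusters coherent); the same world for the rank contrast (species-rank GAM
deviance explained must exceed family-rank; species Mantel p < 0.05; a
cosmopolitan control — occupancy independent of temperature — must not
reject). For recovery, `min_large_clusters` is set to the planted province
count (6) rather than the real-data default of 10: demanding more large
clusters than provinces exist would force over-splitting by construction.
Mantel calibration uses 30 cells, 999 permutations and 500 replicates;
linkage verification uses 200 random matrices of up to 10 leaves; nMDS in
the validation suite uses 10 restarts (the default remains 100), which is
ample at these matrix sizes where restarts converge to the same optimum.

## Known limitations

* The equal-area grid is anchored at the natural origin; analyses at
  realistic scales are insensitive to the anchor, but cell memberships of
  individual records near cell boundaries are convention-dependent.
* The coherence index is constructed for square-cell grids; other
  tessellations would need a re-derived neighbourhood term.
* `N̂` uses grid-index adjacency, which diverges from geographic adjacency
  in the highest-latitude rows.
* The GAM reports association, not causation; deviance explained by SST
  conflates temperature with anything latitudinally structured.
* Raster I/O is plain gridded CSV (latitude rows × longitude columns);
  georeferenced binary formats are out of scope.
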