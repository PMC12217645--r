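# shelfprov

Distance-based biogeographic regionalisation of gridded occurrence data,
with a Cluster Coherence Index.

## What this package is for

Biogeographers who work with large occurrence-database extracts (GBIF/OBIS
style tables) face a recurring pipeline: clean noisy records, bin them on an
equal-area grid, measure compositional turnover between cells, cluster the
cells into candidate provinces, decide which clusters are geographically
meaningful, and test how strongly the resulting structure is coupled to the
environment — classically, sea-surface temperature. `shelfprov` implements
that pipeline end to end for shallow-water (shelf) faunas analysed at
several systematic ranks (species, genus, family), and validates every
stage against a synthetic world with planted provinces.

The core quantitative pieces are:

* **Simpson (turnover) dissimilarity** between cells,
  `beta_sim = min(b, c) / (a + min(b, c))`, where `a` is the number of
  shared taxa and `b`, `c` the numbers unique to each cell — the turnover
  component of the Sørensen index, insensitive to richness differences.
* **UPGMA / WPGMA clustering** of the cell dissimilarity matrix, validated
  by the cophenetic correlation coefficient, with an **objective
  cut-off-selection rule**: the upper cutting height is the largest at
  which at least 10 large clusters (≥ 5 cells) remain, the lower is the
  smallest at which ≥ 95 % of cells belong to large clusters, and levels
  are spaced at a 0.04 distance interval in between.
* The **Cluster Coherence Index**

  ```
  I_CC = sqrt( (d̄ + d̄ (1 − N̂)) / (e √c) )
  ```

  where `c` is the cluster's cell count, `d̄` the mean pairwise haversine
  distance among its cell centroids, `e` the cell edge length, and `N̂` the
  proportion of cells with at least one same-cluster cell in their 3 × 3
  neighbourhood. `I_CC ≤ 1` marks a geographically coherent cluster,
  `I_CC > 1` the presence of outliers, `I_CC > 2` an incoherent cluster.
  The index is unitless and scaled for cell size.
* **Temperature coupling**: non-metric multidimensional scaling of the
  dissimilarities (Kruskal stress-1, 100 random restarts), a GAM smooth
  surface of per-cell mean SST over the ordination (adjusted R² and
  deviance explained), and one-sided permutation Mantel tests between
  taxonomic and temperature distances.

## Worked example

Build a synthetic world (6 planted provinces of 40 cells on a 250-km
Behrmann grid, 80 species per province, a latitudinal SST gradient), sample
records, and run the regionalisation:

```r
library(shelfprov)

w   <- build_world(world_config(seed = 1))
occ <- sample_occurrences(w)            # ~12,000 Darwin-Core-like records
inc <- build_incidence(occ, w$grid, "species", taxonomy = w$taxa)
fit <- regionalize(inc, grid = w$grid, min_large_clusters = 6)
print(fit)
```

```
Distance-based regionalisation
  240 cells, linkage: UPGMA
  cophenetic correlation: UPGMA = 0.917, WPGMA = 0.905
Cut-off scheme: range [0.5458, 0.9594], 11 level(s) at 0.04 interval
  levels: 0.5458, 0.5858, 0.6258, 0.6658, 0.7058, 0.7458, 0.7858, 0.8258, 0.8658, 0.9058, 0.9458
```

UPGMA outperforms WPGMA on the cophenetic correlation (0.917 vs 0.905), as
is typical for average linkage on turnover matrices, and the cut-off rule
brackets an objective range of clustering resolutions. At the highest
selected level the solution has 8 large clusters, every one of them
geographically coherent:

```r
print(fit$coherence[[length(fit$coherence)]])
```

```
Cluster coherence report
 cluster  c d_bar n_hat    icc    class
       1 40 840.0     1 0.7289 coherent
       2 40 856.0     1 0.7358 coherent
       ...
       8 15 516.2     1 0.7302 coherent
```

Temperature coupling at the species rank:

```r
sst <- aggregate_sst(w$sst_monthly, w$grid)
d   <- exclude_cells(fit$dist, inc$record_counts)   # < 10 records, extreme means
ord <- nmds(d, k = 2, n_starts = 10, seed = 1)
fit_gam_surface(scale_rotate(ord$points), sst)
mantel_test(d, env_distance(sst[labels(d)]), n_perm = 999, seed = 1)
```

```
SST smooth surface (n = 239, basis 30):
  adjusted R^2 = 0.998, deviance explained = 99.8%
Mantel test: r = 0.360, p = 0.001 (999 permutations, one-sided)
```

Species composition in this world is thermally filtered within provinces,
so the ordination is almost perfectly explained by SST; the same analysis
at family rank (families span provinces and have 15 °C niche breadth)
explains far less — the rank contrast the method is designed to expose.

The whole chain, including QC and per-stage file outputs with a manifest,
runs as one call:

```r
res <- run_pipeline(run_config(seed = 1), out_dir = "run1")
```

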