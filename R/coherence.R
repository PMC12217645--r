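#' Cluster Coherence Index
#'
#' Quantifies the geographic coherence of a cluster of grid cells as
#' \deqn{I_{CC} = \sqrt{\frac{\bar d + \bar d (1 - \hat N)}{e \sqrt{c}}}}
#' where `c` is the number of cells, `d_bar` the mean great-circle distance
#' among all cell centroids, `e` the cell edge length, and `n_hat` the
#' proportion of cells with at least one same-cluster cell in their 3 x 3
#' neighbourhood. The index is unitless (any distance unit, as long as
#' `d_bar` and `e` share it) and scaled for cell size. For a cluster with no
#' disjunct cells (`n_hat = 1`) it scales with distance; for one made only
#' of disjunct cells (`n_hat = 0`) with twice the distance. Values at most 1
#' indicate a coherent cluster, values above 1 the presence of outliers, and
#' values above 2 an incoherent cluster.
#'
#' @param d_bar mean pairwise centroid distance (same unit as `e`).
#' @param n_hat neighbourhood proportion in `[0, 1]`.
#' @param c_cells number of cells in the cluster (>= 1).
#' @param edge cell edge length (> 0).
#' @return the index value (>= 0).
#' @seealso [classify_coherence()], [cluster_coherence()]
#' @export
#' @examples
#' coherence_index(250, 1, 2, 250)    # 0.8409
#' coherence_index(5000, 0, 6, 250)   # 4.041, incoherent
coherence_index <- function(d_bar, n_hat, c_cells, edge) {
  if (any(edge <= 0)) fail("cell edge length must be positive")
  stopifnot(all(c_cells >= 1), all(n_hat >= 0 & n_hat <= 1), all(d_bar >= 0))
  sqrt((d_bar + d_bar * (1 - n_hat)) / (edge * sqrt(c_cells)))
}

#' Classify a coherence index value
#'
#' Boundary values fall in the lower class: `<= 1` coherent, `(1, 2]`
#' outliers present, `> 2` incoherent.
#'
#' @param icc numeric vector of index values (>= 0).
#' @return factor with levels `coherent`, `outliers`, `incoherent`.
#' @export
classify_coherence <- function(icc) {
  if (any(icc < 0)) fail("coherence index cannot be negative")
  cut(icc, breaks = c(-Inf, 1, 2, Inf),
      labels = c("coherent", "outliers", "incoherent"))
}

#' Proportion of cluster cells with a same-cluster neighbour
#'
#' For each member cell, examines the 8 surrounding `(row, col)` grid
#' positions (queen adjacency: touching at least diagonally). The focal cell
#' itself does not count, so a singleton has `n_hat = 0`. Columns wrap at
#' the grid's antimeridian seam (the equal-area grid is periodic in
#' longitude); rows do not wrap.
#'
#' @param cells character vector of member cell ids (`"r<row>_c<col>"`).
#' @param grid the [build_grid()] object the cells live on.
#' @param wrap wrap columns around the full 360-degree band (default TRUE).
#' @return proportion in `[0, 1]`.
#' @export
neighbourhood_fraction <- function(cells, grid, wrap = TRUE) {
  stopifnot(inherits(grid, "ea_grid"))
  cells <- unique(cells)
  rc <- parse_cell_ids(cells)
  ncol_world <- grid_n_cols_world(grid)
  canon <- function(cc) if (wrap) cc %% ncol_world else cc
  key <- paste(rc$row, canon(rc$col))
  has_nb <- vapply(seq_len(nrow(rc)), function(i) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (paste(rc$row[i] + dr, canon(rc$col[i] + dc)) %in% key) return(TRUE)
    }
    FALSE
  }, logical(1))
  mean(has_nb)
}

parse_cell_ids <- function(cells) {
  m <- regmatches(cells, regexec("^r(-?\\d+)_c(-?\\d+)$", cells))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) fail("unparseable cell id(s): %s", paste(cells[bad], collapse = ", "))
  data.frame(row = as.integer(vapply(m, `[`, "", 2)),
             col = as.integer(vapply(m, `[`, "", 3)))
}

#' Mean pairwise haversine distance among cell centroids
#'
#' Great-circle distances over all unordered centroid pairs, on a sphere of
#' radius 6371.0088 km (WGS84 centroid longitude/latitude). A singleton
#' cluster has no pairs and returns 0 by convention.
#'
#' @param cells character vector of member cell ids.
#' @param grid the [build_grid()] object.
#' @return mean distance in km.
#' @export
mean_centroid_distance <- function(cells, grid) {
  stopifnot(inherits(grid, "ea_grid"))
  cells <- unique(cells)
  idx <- match(cells, grid$cells$cell)
  if (anyNA(idx)) fail("cells not on grid: %s",
                       paste(cells[is.na(idx)], collapse = ", "))
  if (length(cells) < 2) return(0)
  pts <- cbind(grid$cells$lon[idx], grid$cells$lat[idx])
  dm <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000))
  mean(dm[lower.tri(dm)]) / 1000
}

#' Coherence report for a cluster solution
#'
#' Computes `c`, `d_bar`, `n_hat`, the Cluster Coherence Index and its class
#' for every large cluster of a solution. Grey (small) clusters are skipped,
#' as they are not considered for interpretation.
#'
#' @param solution a [cut_dendrogram()] / `cut()` cluster solution, or a
#'   named vector/factor of cluster labels (names = cell ids) in which case
#'   all clusters are scored.
#' @param grid the [build_grid()] object the cells live on.
#' @return a data.frame of class `coherence_report` with columns `cluster`,
#'   `c`, `d_bar`, `n_hat`, `icc`, `class`.
#' @export
cluster_coherence <- function(solution, grid) {
  if (inherits(solution, "cluster_solution")) {
    labels <- solution$labels
    keep <- names(labels)[labels %in% solution$large_clusters]
    labels <- labels[keep]
  } else {
    labels <- solution
    if (is.null(names(labels))) fail("labels must be named by cell id")
  }
  e <- grid$edge_km
  out <- do.call(rbind, lapply(split(names(labels), labels), function(cells) {
    d_bar <- mean_centroid_distance(cells, grid)
    n_hat <- neighbourhood_fraction(cells, grid)
    icc <- coherence_index(d_bar, n_hat, length(cells), e)
    data.frame(c = length(cells), d_bar = d_bar, n_hat = n_hat, icc = icc)
  }))
  out <- data.frame(cluster = rownames(out), out, row.names = NULL)
  out$class <- classify_coherence(out$icc)
  class(out) <- c("coherence_report", "data.frame")
  out
}

#' @export
print.coherence_report <- function(x, ...) {
  cat("Cluster coherence report\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Coherence index across cell sizes
#'
#' Re-renders the same cluster shape (given as relative `(row, col)`
#' offsets) on grids of different cell edge lengths, anchored near the
#' equator, and reports the index profile. Because the index is scaled for
#' cell size, the profile is expected to stay nearly flat over the
#' biogeographically useful range and depart only at implausibly large
#' edges (above ~1e5 km the grid no longer fits the sphere).
#'
#' @param offsets 2-column matrix or data.frame of `(row, col)` cell offsets
#'   describing the cluster shape.
#' @param edges_km numeric vector of cell edge lengths to test.
#' @return data.frame with columns `e` and `icc`.
#' @export
cell_size_robustness <- function(offsets, edges_km) {
  offsets <- as.matrix(offsets)
  stopifnot(ncol(offsets) == 2, all(edges_km > 0))
  out <- lapply(edges_km, function(e) {
    # keep the shape centred on the equator so it fits the sphere
    g <- build_grid(e, c(-179.9, 179.9, -89.9, 89.9))
    rows <- offsets[, 1] - round(mean(range(offsets[, 1])))
    cols <- offsets[, 2] - min(offsets[, 2])
    ids <- sprintf("r%d_c%d", rows, cols)
    ok <- ids %in% g$cells$cell
    if (!all(ok)) return(data.frame(e = e, icc = NA_real_))
    d_bar <- mean_centroid_distance(ids, g)
    n_hat <- neighbourhood_fraction(ids, g)
    data.frame(e = e, icc = coherence_index(d_bar, n_hat, length(ids), e))
  })
  do.call(rbind, out)
}
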