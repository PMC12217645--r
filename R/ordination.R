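#' Non-metric multidimensional scaling with random restarts
#'
#' Embeds a dissimilarity matrix in `k` dimensions by iterative majorisation
#' with monotone (isotonic) regression on dissimilarity ranks (the engine is
#' `vegan::monoMDS`, global model, Kruskal stress-1). The first start is the
#' metric (principal-coordinates) configuration; the remaining
#' `n_starts - 1` are random. The lowest-stress configuration wins. Fully
#' deterministic for a given seed.
#'
#' @param d a `dist` (after cell exclusions, see [exclude_cells()]).
#' @param k number of dimensions (>= 1).
#' @param n_starts number of initialisations (default 100).
#' @param seed integer seed.
#' @param maxit inner iteration cap per start (default 500).
#' @return an object of class `nmds_fit`: list with `points` (n x k matrix),
#'   `stress` (Kruskal stress-1), `k`, `n_starts`, `seed`, `converged`,
#'   `best_start`.
#' @export
nmds <- function(d, k = 2, n_starts = 100, seed = 1, maxit = 500) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  stopifnot(k >= 1, n_starts >= 1)
  if (n < k + 2) fail("need at least k + 2 = %d points", k + 2)
  best <- NULL
  best_start <- NA_integer_
  for (s in seq_len(n_starts)) {
    init <- if (s == 1) {
      y <- stats::cmdscale(d, k = k)
      if (ncol(y) < k) # degenerate metric start: pad with small noise
        y <- cbind(y, matrix(stats::rnorm(n * (k - ncol(y)), sd = 1e-4),
                             n, k - ncol(y)))
      y
    } else {
      set.seed(derive_seed(seed, paste0("nmds_start_", s)))
      matrix(stats::rnorm(n * k), n, k)
    }
    fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                          maxit = maxit, smin = 1e-7, sfgrmin = 1e-7)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best_start <- s
    }
  }
  pts <- best$points
  rownames(pts) <- attr(d, "Labels")
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress, k = k,
                 n_starts = n_starts, seed = seed,
                 converged = isTRUE(best$icause %in% c(3, 4)) ||
                   best$iters < maxit,
                 best_start = best_start),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("nMDS (k = %d, %d starts): stress = %.4f%s\n", x$k, x$n_starts,
              x$stress, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Rotate ordination scores to principal axes and scale to [0, 1]
#'
#' Axes are re-ordered by variance (principal-axis rotation), each axis'
#' sign is fixed so that its largest-magnitude score is positive (making
#' the output invariant to rotations and reflections of the input), and
#' every axis is min-max scaled to `[0, 1]`. A zero-variance axis is set to
#' the constant 0.5 and flagged in the `degenerate_axes` attribute.
#'
#' @param coords numeric matrix of ordination scores (rows = cells).
#' @return the transformed matrix, per-axis min 0 and max 1.
#' @export
scale_rotate <- function(coords) {
  x <- as.matrix(coords)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  sc <- pc$x
  for (j in seq_len(ncol(sc))) {
    i <- which.max(abs(sc[, j]))
    if (sc[i, j] < 0) sc[, j] <- -sc[, j]
  }
  degenerate <- integer(0)
  for (j in seq_len(ncol(sc))) {
    rng <- range(sc[, j])
    if (diff(rng) < 1e-12) {
      sc[, j] <- 0.5
      degenerate <- c(degenerate, j)
    } else sc[, j] <- (sc[, j] - rng[1]) / diff(rng)
  }
  colnames(sc) <- colnames(coords) %||% paste0("NMDS", seq_len(ncol(sc)))
  rownames(sc) <- rownames(coords)
  attr(sc, "degenerate_axes") <- degenerate
  sc
}

#' Radial colour coding of scaled ordination scores
#'
#' HSV mapping for visual comparison of ordinations: hue from the angular
#' position of each point about the centroid of the first two (scaled)
#' axes, saturation from the square root of the relative radial distance
#' (the square-rooted radial gradient spreads colour into the crowded
#' centre), and any extra axes darken the value channel. The centroid is
#' neutral (zero saturation). Deterministic; intended for visual QA.
#'
#' @param coords scaled ordination scores from [scale_rotate()], k in 2..4.
#' @return character vector of hex colours, named by row.
#' @export
radial_colors <- function(coords) {
  x <- as.matrix(coords)
  if (ncol(x) < 2 || ncol(x) > 4) fail("radial colours need 2 to 4 axes")
  ctr <- colMeans(x[, 1:2, drop = FALSE])
  dx <- x[, 1] - ctr[1]
  dy <- x[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  hue <- (atan2(dy, dx) / (2 * pi)) %% 1
  sat <- if (max(r) > 0) sqrt(r / max(r)) else rep(0, length(r))
  val <- rep(1, nrow(x))
  if (ncol(x) >= 3) val <- 1 - 0.5 * rowMeans(x[, 3:ncol(x), drop = FALSE])
  stats::setNames(grDevices::hsv(hue, sat, pmin(pmax(val, 0), 1)),
                  rownames(x))
}

#' Aggregate monthly SST rasters to per-cell means
#'
#' First averages the co-registered monthly rasters into a single temporal
#' mean field, then takes the spatial mean of the field's samples within
#' each grid cell. Cells containing no raster sample come back `NA`.
#'
#' @param rasters list of co-registered [grid_raster()]s (e.g. 12 months).
#' @param grid an [build_grid()] object.
#' @return named numeric vector of mean SST per grid cell.
#' @export
aggregate_sst <- function(rasters, grid) {
  if (length(rasters) == 0) fail("empty raster list")
  ref <- rasters[[1]]
  for (r in rasters)
    if (!identical(r$lon, ref$lon) || !identical(r$lat, ref$lat))
      fail("rasters are not co-registered")
  mean_field <- Reduce(`+`, lapply(rasters, `[[`, "values")) / length(rasters)
  pts <- expand.grid(lon = ref$lon, lat = ref$lat, KEEP.OUT.ATTRS = FALSE)
  v <- as.vector(t(mean_field))
  p <- behrmann_project(pts$lon, pts$lat)
  id <- sprintf("r%d_c%d", floor(p$y / grid$edge_km),
                floor(p$x / grid$edge_km))
  keep <- id %in% grid$cells$cell & !is.na(v)
  means <- tapply(v[keep], id[keep], mean)
  out <- stats::setNames(rep(NA_real_, nrow(grid$cells)), grid$cells$cell)
  out[names(means)] <- as.numeric(means)
  out
}

#' Pairwise environmental (Euclidean) distances
#'
#' @param values named numeric vector of per-cell environmental values.
#' @return a `dist` of absolute pairwise differences.
#' @export
env_distance <- function(values) {
  values <- values[!is.na(values)]
  stats::dist(values)
}

#' Fit a smooth temperature surface to an ordination
#'
#' Gaussian generalised additive model `sst ~ s(axis1, ..., axisk)` with a
#' penalised thin-plate spline basis and smoothing chosen by generalised
#' cross-validation. Reports the adjusted R-squared and deviance explained
#' (1 - residual deviance / null deviance) as the measures of match between
#' temperature and ordination structure.
#'
#' @param coords ordination scores (rows named by cell).
#' @param sst named numeric vector of per-cell SST.
#' @param basis_dim maximum basis dimension (default 30, shrunk with a flag
#'   when fewer cells are available).
#' @return an object of class `env_surface`: list with `model`,
#'   `adjusted_r2`, `deviance_explained`, `basis_dim`, `shrunk`, `n`.
#' @export
fit_gam_surface <- function(coords, sst, basis_dim = 30) {
  x <- as.matrix(coords)
  common <- intersect(rownames(x), names(sst)[!is.na(sst)])
  if (length(common) < 10) fail("need >= 10 cells with both coordinates and SST")
  x <- x[common, , drop = FALSE]
  df <- data.frame(sst = as.numeric(sst[common]), x)
  axes <- colnames(x) <- paste0("A", seq_len(ncol(x)))
  names(df) <- c("sst", axes)
  k_use <- min(basis_dim, length(common) - 2)
  shrunk <- k_use < basis_dim
  form <- stats::as.formula(sprintf("sst ~ s(%s, k = %d)",
                                    paste(axes, collapse = ", "), k_use))
  model <- mgcv::gam(form, data = df, method = "GCV.Cp")
  sm <- summary(model)
  de <- as.numeric(sm$dev.expl)
  if (!is.finite(de)) de <- 0 # constant response: null deviance zero
  structure(list(model = model, adjusted_r2 = as.numeric(sm$r.sq),
                 deviance_explained = de,
                 basis_dim = k_use, shrunk = shrunk, n = length(common)),
            class = "env_surface")
}

#' @export
print.env_surface <- function(x, ...) {
  cat(sprintf("SST smooth surface (n = %d, basis %d%s):\n", x$n, x$basis_dim,
              if (x$shrunk) ", shrunk" else ""))
  cat(sprintf("  adjusted R^2 = %.3f, deviance explained = %.1f%%\n",
              x$adjusted_r2, 100 * x$deviance_explained))
  invisible(x)
}

#' Permutation Mantel test
#'
#' Pearson correlation between the condensed vectors of two distance
#' matrices over the same cells, with significance from jointly permuting
#' one matrix's row/column labels. One-sided ("greater") p-value
#' `(1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`, so a negative association
#' yields p near 1.
#'
#' @param d_taxa,d_env `dist` objects on the same cells (aligned by labels
#'   when present).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return an object of class `mantel_result`: list with `r`, `p`,
#'   `n_perm`, `seed`.
#' @export
mantel_test <- function(d_taxa, d_env, n_perm = 999, seed = 1) {
  m1 <- as.matrix(d_taxa)
  m2 <- as.matrix(d_env)
  l1 <- rownames(m1)
  l2 <- rownames(m2)
  if (!is.null(l1) && !is.null(l2)) {
    common <- intersect(l1, l2)
    if (length(common) < 3) fail("fewer than 3 shared cells")
    m1 <- m1[common, common]
    m2 <- m2[common, common]
  } else if (nrow(m1) != nrow(m2)) fail("matrices differ in size")
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  v2 <- m2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("Mantel r undefined: a matrix is constant")
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = n_perm,
                          seed = seed), class = "mantel_result"))
  }
  r_obs <- stats::cor(v1, v2)
  set.seed(derive_seed(seed, "mantel"))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stats::cor(v1, m2[p, p][lt]) >= r_obs) hits <- hits + 1L
  }
  structure(list(r = r_obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm,
                 seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%d permutations, one-sided)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}
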