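#' Agglomerative clustering of a dissimilarity matrix
#'
#' Average-linkage clustering with either the unweighted (UPGMA) or weighted
#' (WPGMA) pair-group method. UPGMA updates merged-group distances as
#' size-weighted means; WPGMA as simple means of the two merged groups'
#' distances.
#'
#' @param d a `dist` (symmetric, finite, zero diagonal).
#' @param method `"UPGMA"` or `"WPGMA"`.
#' @return an `hclust` object with `$method` set to the pair-group name.
#' @export
agglomerate <- function(d, method = c("UPGMA", "WPGMA")) {
  method <- match.arg(method)
  d <- stats::as.dist(d)
  if (any(!is.finite(d))) fail("dissimilarity matrix contains non-finite entries")
  if (attr(d, "Size") < 2) fail("need at least 2 leaves")
  hc <- stats::hclust(d, method = if (method == "UPGMA") "average" else "mcquitty")
  hc$method <- method
  hc
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise dissimilarities and the
#' cophenetic distances (the dendrogram height at which each pair first
#' joins). Measures how faithfully the tree represents the matrix.
#'
#' @param hc an `hclust` tree built from `d`'s leaves.
#' @param d the original `dist`.
#' @return correlation in `[-1, 1]`; `NA` with a warning when either vector
#'   has zero variance (e.g. only one pair).
#' @export
cophenetic_correlation <- function(hc, d) {
  coph <- stats::cophenetic(hc)
  d <- stats::as.dist(d)
  if (attr(d, "Size") != attr(coph, "Size"))
    fail("tree and matrix have different numbers of leaves")
  # align by labels when present
  if (!is.null(attr(d, "Labels")) && !is.null(attr(coph, "Labels"))) {
    m <- as.matrix(coph)[attr(d, "Labels"), attr(d, "Labels")]
    coph <- stats::as.dist(m)
  }
  x <- as.vector(d)
  y <- as.vector(coph)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || length(x) < 2) {
    warning("cophenetic correlation undefined (zero variance or single pair)")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Choose the better-supported linkage method
#'
#' Fits both UPGMA and WPGMA and returns the method with the higher
#' cophenetic correlation (both values are reported). An exact tie falls to
#' UPGMA with a flag.
#'
#' @param d a `dist` with at least 3 leaves.
#' @return list with `method`, `cophenetic` (named numeric length 2),
#'   `trees` (both `hclust` objects) and `tie` flag.
#' @export
select_method <- function(d) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 3) fail("need at least 3 leaves to compare methods")
  trees <- list(UPGMA = agglomerate(d, "UPGMA"), WPGMA = agglomerate(d, "WPGMA"))
  cc <- vapply(trees, cophenetic_correlation, numeric(1), d = d)
  tie <- isTRUE(cc[["UPGMA"]] == cc[["WPGMA"]])
  method <- if (tie || cc[["UPGMA"]] >= cc[["WPGMA"]]) "UPGMA" else "WPGMA"
  list(method = method, cophenetic = cc, trees = trees, tie = tie)
}

#' Arithmetic cut-off level sequence
#'
#' Levels anchored at the lower threshold and stepped upward by `interval`
#' while they fit below the upper threshold (inclusive, with a small
#' numerical tolerance).
#'
#' @param lower,upper distance thresholds, `lower <= upper`.
#' @param interval spacing (default 0.04).
#' @return numeric vector of levels.
#' @export
#' @examples
#' cutoff_levels(0.82, 0.94, 0.04) # 0.82 0.86 0.90 0.94
cutoff_levels <- function(lower, upper, interval = 0.04) {
  if (interval <= 0) fail("interval must be positive")
  if (lower > upper) fail("lower threshold exceeds upper")
  n <- floor((upper - lower) / interval + 1e-9)
  lower + interval * (0:n)
}

#' Objective dendrogram cut-off selection
#'
#' Constrains the relevant range of cutting heights without a subjective
#' choice: the upper threshold is the largest merge height at which cutting
#' still yields at least `min_large_clusters` large clusters (clusters with
#' at least `min_size` cells), and the lower threshold is the smallest merge
#' height at which at least a fraction `coverage` of all cells belongs to
#' large clusters. Between the thresholds, as many levels as fit at an
#' `interval` spacing are laid out, anchored at the lower threshold.
#'
#' @param hc an `hclust` tree.
#' @param min_size minimum cells for a "large" cluster (default 5).
#' @param min_large_clusters required number of large clusters at the upper
#'   threshold (default 10).
#' @param coverage required fraction of cells in large clusters at the lower
#'   threshold (default 0.95).
#' @param interval level spacing (default 0.04).
#' @return an object of class `cutoff_scheme`: list with `lower`, `upper`,
#'   `levels` and `curves` (data.frame `h`, `n_large`, `coverage` evaluated
#'   at every merge height).
#' @export
select_cutoffs <- function(hc, min_size = 5, min_large_clusters = 10,
                           coverage = 0.95, interval = 0.04) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels %||% hc$order)
  heights <- sort(unique(hc$height))
  curves <- do.call(rbind, lapply(heights, function(h) {
    sizes <- table(stats::cutree(hc, h = h))
    large <- sizes[sizes >= min_size]
    data.frame(h = h, n_large = length(large), coverage = sum(large) / n)
  }))
  ok_upper <- curves$h[curves$n_large >= min_large_clusters]
  ok_lower <- curves$h[curves$coverage >= coverage]
  if (length(ok_upper) == 0 || length(ok_lower) == 0 ||
      max(ok_upper) < min(ok_lower))
    fail(paste0("no feasible cut-off range: max height with >= %d large ",
                "clusters is %s, min height with coverage >= %g is %s"),
         min_large_clusters,
         if (length(ok_upper)) format(max(ok_upper)) else "none",
         coverage,
         if (length(ok_lower)) format(min(ok_lower)) else "none")
  lower <- min(ok_lower)
  upper <- max(ok_upper)
  structure(list(lower = lower, upper = upper,
                 levels = cutoff_levels(lower, upper, interval),
                 interval = interval, min_size = min_size,
                 min_large_clusters = min_large_clusters,
                 coverage = coverage, curves = curves),
            class = "cutoff_scheme")
}

#' @export
print.cutoff_scheme <- function(x, ...) {
  cat(sprintf("Cut-off scheme: range [%.4g, %.4g], %d level(s) at %.3g interval\n",
              x$lower, x$upper, length(x$levels), x$interval))
  cat("  levels:", paste(format(x$levels, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Cut a dendrogram into a cluster solution
#'
#' Cuts at height `h` (merges with height <= h joined) and flags clusters
#' with fewer than `min_size` cells as grey: they are kept in the labels but
#' excluded from summaries and coherence scoring. Clusters are renumbered by
#' decreasing size.
#'
#' @param hc an `hclust` tree.
#' @param h cutting height.
#' @param min_size minimum size of a large cluster (default 5).
#' @return an object of class `cluster_solution`: list with `cutoff`,
#'   `labels` (named integer vector), `sizes`, `large_clusters`,
#'   `grey_cells`, `min_size`.
#' @export
cut_dendrogram <- function(hc, h, min_size = 5) {
  stopifnot(inherits(hc, "hclust"))
  raw <- stats::cutree(hc, h = h)
  sizes <- sort(table(raw), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- relab[as.character(raw)]
  names(labels) <- names(raw)
  sizes <- table(labels)
  large <- as.integer(names(sizes)[sizes >= min_size])
  structure(list(cutoff = h, labels = labels,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 large_clusters = large,
                 grey_cells = names(labels)[!(labels %in% large)],
                 min_size = min_size),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution at h = %.4g: %d clusters (%d large, >= %d cells), %d grey cell(s)\n",
              x$cutoff, length(x$sizes), length(x$large_clusters), x$min_size,
              length(x$grey_cells)))
  invisible(x)
}

#' Core statistics and inter-cluster dissimilarities for a solution
#'
#' For each large cluster: number of cells, pooled taxon richness, and
#' endemism (fraction of the cluster's taxa found in no other large
#' cluster). Also returns the Simpson dissimilarity matrix among clusters,
#' computed on the pooled (union) taxon sets of their member cells.
#'
#' @param solution a [cut_dendrogram()] solution.
#' @param incidence the [build_incidence()] matrix the solution was fitted
#'   on.
#' @return list with `stats` (data.frame `cluster`, `n_cells`, `n_taxa`,
#'   `endemism`) and `between` (`dist` of inter-cluster Simpson values;
#'   `NULL` with fewer than 2 large clusters).
#' @export
cluster_summaries <- function(solution, incidence) {
  stopifnot(inherits(solution, "cluster_solution"),
            inherits(incidence, "incidence_matrix"))
  labels <- solution$labels[intersect(names(solution$labels), incidence$cells)]
  large <- solution$large_clusters
  pooled <- lapply(large, function(cl) {
    cells <- names(labels)[labels == cl]
    incidence$taxa[colSums(incidence$values[cells, , drop = FALSE]) > 0]
  })
  names(pooled) <- as.character(large)
  all_counts <- table(unlist(pooled))
  stats_df <- do.call(rbind, lapply(seq_along(pooled), function(i) {
    taxa <- pooled[[i]]
    endemic <- sum(all_counts[taxa] == 1)
    data.frame(cluster = large[i],
               n_cells = sum(labels == large[i]),
               n_taxa = length(taxa),
               endemism = if (length(taxa)) endemic / length(taxa) else NA_real_)
  }))
  between <- NULL
  if (length(pooled) >= 2) {
    k <- length(pooled)
    m <- matrix(0, k, k, dimnames = list(names(pooled), names(pooled)))
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      m[i, j] <- m[j, i] <- simpson_pair(pooled[[i]], pooled[[j]])
    between <- stats::as.dist(m)
  }
  list(stats = stats_df, between = between)
}

#' Fit a distance-based regionalisation
#'
#' The central fitting function: from a per-rank incidence matrix (or a
#' ready-made dissimilarity `dist`), computes Simpson turnover
#' dissimilarities among cells, fits UPGMA and WPGMA trees, keeps the one
#' with the higher cophenetic correlation, derives the objective cut-off
#' scheme, and cuts the tree at every level. When a grid is supplied, each
#' solution's large clusters are scored with the Cluster Coherence Index.
#'
#' @param x an [build_incidence()] object or a `dist` of cell
#'   dissimilarities.
#' @param grid optional [build_grid()] object (enables coherence scoring).
#' @param min_size,min_large_clusters,coverage,interval cut-off-selection
#'   parameters, see [select_cutoffs()].
#' @param method `"auto"` (cophenetic selection), `"UPGMA"` or `"WPGMA"`.
#' @return an object of class `regionalization`; see [print.regionalization()].
#' @export
#' @examples
#' \donttest{
#' w <- build_world(world_config(n_provinces = 3, cells_per_province = 10,
#'                               n_species_per_province = 25, seed = 7))
#' occ <- sample_occurrences(w)
#' inc <- build_incidence(occ, w$grid, "species", taxonomy = w$taxa)
#' fit <- regionalize(inc, grid = w$grid, min_large_clusters = 3)
#' print(fit)
#' }
regionalize <- function(x, grid = NULL, min_size = 5, min_large_clusters = 10,
                        coverage = 0.95, interval = 0.04,
                        method = c("auto", "UPGMA", "WPGMA")) {
  method <- match.arg(method)
  cl <- match.call()
  incidence <- NULL
  if (inherits(x, "incidence_matrix")) {
    incidence <- x
    d <- simpson_matrix(x)
  } else d <- stats::as.dist(x)
  if (method == "auto") {
    sel <- select_method(d)
  } else {
    tr <- agglomerate(d, method)
    sel <- list(method = method,
                cophenetic = stats::setNames(cophenetic_correlation(tr, d), method),
                trees = stats::setNames(list(tr), method), tie = FALSE)
  }
  hc <- sel$trees[[sel$method]]
  scheme <- select_cutoffs(hc, min_size = min_size,
                           min_large_clusters = min_large_clusters,
                           coverage = coverage, interval = interval)
  solutions <- lapply(scheme$levels, cut_dendrogram, hc = hc, min_size = min_size)
  names(solutions) <- format(scheme$levels, digits = 4)
  coherence <- NULL
  if (!is.null(grid))
    coherence <- lapply(solutions, cluster_coherence, grid = grid)
  structure(list(call = cl, dist = d, method = sel$method,
                 cophenetic = sel$cophenetic, tie = sel$tie, tree = hc,
                 trees = sel$trees, scheme = scheme, solutions = solutions,
                 coherence = coherence, incidence = incidence, grid = grid),
            class = "regionalization")
}

#' @export
print.regionalization <- function(x, ...) {
  cat("Distance-based regionalisation\n")
  cat(sprintf("  %d cells, linkage: %s%s\n", attr(x$dist, "Size"), x$method,
              if (isTRUE(x$tie)) " (cophenetic tie)" else ""))
  cat("  cophenetic correlation:",
      paste(sprintf("%s = %.3f", names(x$cophenetic), x$cophenetic),
            collapse = ", "), "\n")
  print(x$scheme)
  invisible(x)
}

#' @export
summary.regionalization <- function(object, ...) {
  tab <- do.call(rbind, lapply(seq_along(object$solutions), function(i) {
    s <- object$solutions[[i]]
    row <- data.frame(cutoff = s$cutoff, clusters = length(s$sizes),
                      large = length(s$large_clusters),
                      grey_cells = length(s$grey_cells))
    if (!is.null(object$coherence)) {
      cls <- object$coherence[[i]]$class
      row$coherent <- sum(cls == "coherent")
      row$outliers <- sum(cls == "outliers")
      row$incoherent <- sum(cls == "incoherent")
    }
    row
  }))
  out <- list(method = object$method, cophenetic = object$cophenetic,
              scheme = object$scheme, table = tab)
  class(out) <- "summary.regionalization"
  out
}

#' @export
print.summary.regionalization <- function(x, ...) {
  cat(sprintf("Regionalisation summary (linkage %s)\n", x$method))
  cat("  cophenetic correlation:",
      paste(sprintf("%s = %.3f", names(x$cophenetic), x$cophenetic),
            collapse = ", "), "\n")
  print.data.frame(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Cut a fitted regionalisation at a new height
#'
#' @param x a [regionalize()] fit.
#' @param h cutting height; defaults to the scheme's upper threshold.
#' @param ... unused.
#' @return a `cluster_solution`.
#' @export
cut.regionalization <- function(x, h = NULL, ...) {
  cut_dendrogram(x$tree, h %||% x$scheme$upper, min_size = x$scheme$min_size)
}

#' Plot a fitted regionalisation dendrogram
#'
#' Draws the selected tree with the cut-off levels as horizontal lines.
#'
#' @param x a [regionalize()] fit.
#' @param ... passed to `plot.hclust`.
#' @export
plot.regionalization <- function(x, ...) {
  graphics::plot(x$tree, hang = -1, labels = FALSE, main = "Regionalisation",
                 xlab = "", sub = "", ylab = "Simpson distance", ...)
  graphics::abline(h = x$scheme$levels, col = "grey50", lty = 2)
  graphics::abline(h = c(x$scheme$lower, x$scheme$upper), col = "red3", lty = 1)
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are height differences, so leaf depth equals merge height.
#'
#' @param hc an `hclust` tree (or a [regionalize()] fit).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  if (inherits(hc, "regionalization")) hc <- hc$tree
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
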