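test_that("linkage reproduces hand-run merge sequences", {
  # two leaves: a single merge at their distance for both methods
  d2 <- stats::as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  for (m in c("UPGMA", "WPGMA"))
    expect_equal(agglomerate(d2, m)$height, 0.4)
  # two tight pairs: merges at 0.1, 0.1, then 0.9 (average of all cross pairs)
  m4 <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m4[1, 2] <- m4[2, 1] <- 0.1
  m4[3, 4] <- m4[4, 3] <- 0.1
  diag(m4) <- 0
  for (meth in c("UPGMA", "WPGMA"))
    expect_equal(sort(agglomerate(stats::as.dist(m4), meth)$height),
                 c(0.1, 0.1, 0.9))
  expect_error(agglomerate(stats::as.dist(matrix(c(0, NA, NA, 0), 2))),
               "non-finite")
})

test_that("merge heights match the naive O(n^3) oracle on random matrices", {
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- random_dissimilarity(n, seed = 100 + i)
    for (meth in c("UPGMA", "WPGMA")) {
      hc <- agglomerate(d, meth)
      oracle <- naive_linkage(d, meth)
      expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
      # cophenetic matrices agree too
      expect_equal(unname(as.matrix(stats::cophenetic(hc))[paste0("L", 1:n),
                                                           paste0("L", 1:n)]),
                   unname(oracle$coph), tolerance = 1e-12)
    }
  }
})

test_that("cophenetic correlation is exact for ultrametric input, flagged when degenerate", {
  # build an ultrametric matrix from a tree, feed it back: correlation 1
  d <- random_dissimilarity(8, seed = 5)
  hc <- agglomerate(d, "UPGMA")
  ultra <- stats::cophenetic(hc)
  hc2 <- agglomerate(ultra, "UPGMA")
  expect_equal(cophenetic_correlation(hc2, ultra), 1, tolerance = 1e-10)
  # 2-leaf case: a single pair has no variance
  d2 <- stats::as.dist(matrix(c(0, 0.4, 0.4, 0), 2))
  expect_warning(v <- cophenetic_correlation(agglomerate(d2), d2), "undefined")
  expect_true(is.na(v))
})

test_that("cophenetic matrices are ultrametric on every triple", {
  for (i in 1:5) {
    d <- random_dissimilarity(7, seed = 200 + i)
    for (meth in c("UPGMA", "WPGMA"))
      expect_true(is_ultrametric(as.matrix(stats::cophenetic(
        agglomerate(d, meth)))))
  }
})

test_that("method selection reports both correlations and flags ties", {
  d <- random_dissimilarity(9, seed = 31)
  sel <- select_method(d)
  expect_true(sel$method %in% c("UPGMA", "WPGMA"))
  expect_true(all(sel$cophenetic >= -1 & sel$cophenetic <= 1))
  expect_named(sel$cophenetic, c("UPGMA", "WPGMA"))
  # ultrametric input: both represent it exactly -> tie, UPGMA wins flagged
  ultra <- stats::cophenetic(agglomerate(d, "UPGMA"))
  sel2 <- select_method(ultra)
  expect_equal(sel2$method, "UPGMA")
  expect_true(sel2$tie)
})

test_that("cut-off level sequences are anchored at the lower threshold", {
  expect_equal(cutoff_levels(0.82, 0.94, 0.04), c(0.82, 0.86, 0.90, 0.94))
  expect_equal(cutoff_levels(0.67, 0.76, 0.04), c(0.67, 0.71, 0.75))
  expect_equal(cutoff_levels(0.44, 0.50, 0.04), c(0.44, 0.48))
  expect_equal(cutoff_levels(0.5, 0.5, 0.04), 0.5)
  expect_error(cutoff_levels(0.9, 0.8), "exceeds")
  expect_error(cutoff_levels(0.1, 0.9, -0.04), "positive")
})

test_that("cut-off selection satisfies its defining constraints", {
  # planted: 12 provinces of 5 leaves, within 0.2, between 0.9
  k <- 12; s <- 5
  m <- matrix(0.9, k * s, k * s)
  for (g in seq_len(k)) {
    i <- ((g - 1) * s + 1):(g * s)
    m[i, i] <- 0.2
  }
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("c", seq_len(k * s))
  hc <- agglomerate(stats::as.dist(m), "UPGMA")
  sch <- select_cutoffs(hc, min_size = 5, min_large_clusters = 10,
                        coverage = 0.95, interval = 0.04)
  expect_gte(sch$upper, 0.2)
  expect_lt(sch$upper, 0.9)
  # at every level the 12 planted provinces are the large clusters
  for (h in sch$levels) {
    sol <- cut_dendrogram(hc, h, min_size = 5)
    expect_length(sol$large_clusters, 12)
    expect_length(sol$grey_cells, 0)
  }
  # unconstrained: full height range of the dendrogram
  sch2 <- select_cutoffs(hc, min_size = 5, min_large_clusters = 1,
                         coverage = 0)
  expect_equal(sch2$lower, min(hc$height))
  expect_equal(sch2$upper, max(hc$height))
  # infeasible: demanding more large clusters than leaves allow
  expect_error(select_cutoffs(hc, min_size = 5, min_large_clusters = 50),
               "no feasible")
})

test_that("cutting behaves at the extremes and is monotone in height", {
  d <- random_dissimilarity(20, seed = 77)
  hc <- agglomerate(d, "UPGMA")
  s0 <- cut_dendrogram(hc, 0, min_size = 5)
  expect_length(s0$sizes, 20)          # every leaf its own cluster
  expect_length(s0$grey_cells, 20)     # all singletons are grey
  s1 <- cut_dendrogram(hc, max(hc$height) + 1, min_size = 5)
  expect_length(s1$sizes, 1)
  hs <- sort(unique(hc$height))
  n_clusters <- vapply(hs, function(h) length(cut_dendrogram(hc, h)$sizes),
                       numeric(1))
  cover <- vapply(hs, function(h) {
    s <- cut_dendrogram(hc, h, min_size = 3)
    1 - length(s$grey_cells) / 20
  }, numeric(1))
  expect_true(all(diff(n_clusters) <= 0))
  expect_true(all(diff(cover) >= 0))
})

test_that("cluster summaries compute endemism and pooled dissimilarities", {
  g <- build_grid(250, c(-10, 10, -10, 10))
  cells <- g$cells$cell[1:4]
  m <- matrix(0L, 4, 6, dimnames = list(cells, paste0("t", 1:6)))
  m[1, 1:4] <- 1L; m[2, 1:4] <- 1L   # cluster 1: taxa t1-t4
  m[3, c(3, 4, 5, 6)] <- 1L; m[4, c(3, 4, 5, 6)] <- 1L # cluster 2: t3-t6
  inc <- structure(list(rank = "species", cells = cells,
                        taxa = paste0("t", 1:6), values = m,
                        record_counts = stats::setNames(rep(10, 4), cells)),
                   class = "incidence_matrix")
  sol <- structure(list(cutoff = 0.5,
                        labels = stats::setNames(c(1L, 1L, 2L, 2L), cells),
                        sizes = c("1" = 2L, "2" = 2L),
                        large_clusters = c(1L, 2L), grey_cells = character(0),
                        min_size = 2), class = "cluster_solution")
  cs <- cluster_summaries(sol, inc)
  # each cluster has 4 taxa, 2 shared -> endemism 0.5, dissimilarity 0.5
  expect_equal(cs$stats$n_taxa, c(4, 4))
  expect_equal(cs$stats$endemism, c(0.5, 0.5))
  expect_equal(as.vector(cs$between), 0.5)
  # disjoint clusters: endemism 1, dissimilarity 1
  m2 <- m; m2[3:4, ] <- 0L; m2[3, 5:6] <- 1L; m2[4, 5:6] <- 1L
  inc2 <- inc; inc2$values <- m2
  cs2 <- cluster_summaries(sol, inc2)
  expect_equal(cs2$stats$endemism, c(1, 1))
  expect_equal(as.vector(cs2$between), 1)
  # single large cluster: all its taxa endemic, no between matrix
  sol1 <- sol; sol1$large_clusters <- 1L; sol1$grey_cells <- cells[3:4]
  cs1 <- cluster_summaries(sol1, inc)
  expect_equal(cs1$stats$endemism, 1)
  expect_null(cs1$between)
})

test_that("the regionalize fitter assembles a coherent object with methods", {
  w <- tiny_world(seed = 41)
  occ <- sample_occurrences(w)
  inc <- build_incidence(occ, w$grid, "species", taxonomy = w$taxa)
  fit <- regionalize(inc, grid = w$grid, min_large_clusters = 3)
  expect_s3_class(fit, "regionalization")
  expect_true(fit$method %in% c("UPGMA", "WPGMA"))
  expect_length(fit$solutions, length(fit$scheme$levels))
  expect_s3_class(fit$coherence[[1]], "coherence_report")
  expect_output(print(fit), "cophenetic")
  sm <- summary(fit)
  expect_equal(nrow(sm$table), length(fit$scheme$levels))
  sol <- cut(fit, h = fit$scheme$upper)
  expect_s3_class(sol, "cluster_solution")
  # newick export parses back to a tree with one tip per cell
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(fit, f)
  tree <- ape::read.tree(f)
  expect_equal(length(tree$tip.label), attr(fit$dist, "Size"))
})
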