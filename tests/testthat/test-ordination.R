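test_that("nMDS recovers planar configurations and is seed-deterministic", {
  set.seed(4)
  pts <- matrix(runif(10), 5, 2)
  d <- stats::dist(pts)
  fit <- nmds(d, k = 2, n_starts = 5, seed = 2)
  expect_lt(fit$stress, 0.01)
  fit2 <- nmds(d, k = 2, n_starts = 5, seed = 2)
  expect_identical(fit$points, fit2$points)
  expect_identical(fit$stress, fit2$stress)
})

test_that("nMDS stress is monotone non-increasing in dimension", {
  d <- random_dissimilarity(12, seed = 3)
  s2 <- nmds(d, k = 2, n_starts = 5, seed = 1)$stress
  s4 <- nmds(d, k = 4, n_starts = 5, seed = 1)$stress
  expect_lte(s4, s2 + 1e-8)
})

test_that("stress is invariant to rigid motion and uniform scaling of input", {
  set.seed(8)
  pts <- matrix(rnorm(20), 10, 2)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  fit_a <- nmds(stats::dist(pts), k = 2, n_starts = 3, seed = 5)
  fit_b <- nmds(stats::dist(3 * pts %*% rot), k = 2, n_starts = 3, seed = 5)
  expect_equal(fit_a$stress, fit_b$stress, tolerance = 1e-6)
})

test_that("scaled rotation fixes range, axis order and reflections", {
  set.seed(6)
  x <- cbind(rnorm(30, sd = 4), rnorm(30, sd = 1))
  rownames(x) <- paste0("c", 1:30)
  s <- scale_rotate(x)
  expect_equal(unname(apply(s, 2, min)), c(0, 0))
  expect_equal(unname(apply(s, 2, max)), c(1, 1))
  # variance ordering: first axis carries more spread before scaling
  pc <- stats::prcomp(x)
  expect_gte(pc$sdev[1], pc$sdev[2])
  # reflecting the input leaves the output unchanged (sign convention)
  expect_equal(scale_rotate(cbind(-x[, 1], x[, 2])), s, tolerance = 1e-9)
  expect_equal(scale_rotate(-x), s, tolerance = 1e-9)
  # degenerate axis pinned to 0.5 and flagged
  z <- cbind(rnorm(10), rep(2, 10))
  sz <- scale_rotate(z)
  expect_true(all(sz[, 2] == 0.5))
  expect_equal(attr(sz, "degenerate_axes"), 2L)
})

test_that("radial colours are neutral at the centroid and complementary opposite", {
  # symmetric set: the centroid coincides with the centre point
  x <- rbind(centre = c(0.5, 0.5), east = c(1, 0.5), west = c(0, 0.5),
             north = c(0.5, 1), south = c(0.5, 0))
  cols <- radial_colors(x)
  hsvs <- grDevices::rgb2hsv(grDevices::col2rgb(cols))
  expect_equal(unname(hsvs["s", "centre"]), 0, tolerance = 1e-6)
  hue_e <- hsvs["h", "east"]; hue_w <- hsvs["h", "west"]
  expect_equal(abs(hue_e - hue_w), 0.5, tolerance = 1e-6)
  # deterministic
  expect_identical(radial_colors(x), cols)
  expect_error(radial_colors(x[, 1, drop = FALSE]), "2 to 4")
})

test_that("SST aggregation averages time first, then space per cell", {
  g <- build_grid(250, c(-10, 10, -10, 10))
  lon <- seq(-10, 10, 0.25)
  lat <- seq(-10, 10, 0.25)
  mk <- function(v) grid_raster(lon, lat, matrix(v, length(lat), length(lon)))
  expect_true(all(abs(aggregate_sst(list(mk(15)), g) - 15) < 1e-9, na.rm = TRUE))
  two <- aggregate_sst(list(mk(10), mk(20)), g)
  expect_true(all(abs(two - 15) < 1e-9, na.rm = TRUE))
  expect_error(aggregate_sst(list(), g), "empty")
  expect_error(aggregate_sst(list(mk(1), grid_raster(lon[-1], lat,
    matrix(1, length(lat), length(lon) - 1))), g), "co-registered")
  # latitudinal gradient: per-cell means decrease with |centroid latitude|
  grad <- grid_raster(lon, lat, matrix(rep(30 - abs(lat), length(lon)),
                                       length(lat), length(lon)))
  v <- aggregate_sst(list(grad), g)
  rows <- g$cells$row[match(names(v), g$cells$cell)]
  keep <- !is.na(v) & rows >= 0
  by_row <- tapply(v[keep], rows[keep], mean)
  expect_true(all(diff(by_row[order(as.integer(names(by_row)))]) < 0))
})

test_that("GAM surfaces separate signal from noise", {
  set.seed(10)
  n <- 200
  coords <- cbind(runif(n), runif(n))
  rownames(coords) <- paste0("c", 1:n)
  # exact smooth function of the ordination: essentially all deviance explained
  sst_smooth <- stats::setNames(20 + 5 * coords[, 1] + 3 * sin(pi * coords[, 2]),
                                rownames(coords))
  fit <- fit_gam_surface(coords, sst_smooth)
  expect_gte(fit$deviance_explained, 0.99)
  # independent noise: little deviance explained
  sst_noise <- stats::setNames(rnorm(n), rownames(coords))
  fit2 <- fit_gam_surface(coords, sst_noise)
  expect_lt(fit2$deviance_explained, 0.15)
  # constant response: nothing to explain
  sst_const <- stats::setNames(rep(12, n), rownames(coords))
  fit3 <- fit_gam_surface(coords, sst_const)
  expect_equal(fit3$deviance_explained, 0)
  expect_lte(fit3$adjusted_r2, 0)
  # small samples shrink the basis with a flag
  small <- fit_gam_surface(coords[1:12, ], sst_smooth[1:12])
  expect_true(small$shrunk)
  expect_error(fit_gam_surface(coords[1:5, ], sst_smooth[1:5]), ">= 10")
})

test_that("deviance explained never decreases with a larger basis", {
  set.seed(13)
  n <- 80
  coords <- cbind(runif(n), runif(n))
  rownames(coords) <- paste0("c", 1:n)
  sst <- stats::setNames(sin(3 * coords[, 1]) + rnorm(n, sd = 0.3),
                         rownames(coords))
  de_small <- fit_gam_surface(coords, sst, basis_dim = 5)$deviance_explained
  de_large <- fit_gam_surface(coords, sst, basis_dim = 25)$deviance_explained
  expect_gte(de_large, de_small - 1e-8)
})

test_that("Mantel test matches its contracts and vegan's statistic", {
  d <- random_dissimilarity(15, seed = 21)
  # identity: perfect correlation at the permutation floor
  mt <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 100)
  # negative association: one-sided p near 1
  m <- as.matrix(d)
  neg <- stats::as.dist(max(m) - m)
  mt2 <- mantel_test(d, neg, n_perm = 99, seed = 1)
  expect_lt(mt2$r, 0)
  expect_gt(mt2$p, 0.9)
  # statistic agrees with the independent vegan implementation
  d2 <- random_dissimilarity(15, seed = 22)
  expect_equal(mantel_test(d, d2, n_perm = 9, seed = 1)$r,
               unname(vegan::mantel(d, d2, permutations = 9)$statistic),
               tolerance = 1e-10)
  # constant matrix: undefined, flagged
  cm <- matrix(1, 5, 5) - diag(5)
  rownames(cm) <- colnames(cm) <- paste0("L", 1:5)
  const <- stats::as.dist(cm)
  expect_warning(mt3 <- mantel_test(const, random_dissimilarity(5, 1)),
                 "constant")
  expect_true(is.na(mt3$r))
  # determinism
  expect_identical(mantel_test(d, d2, n_perm = 99, seed = 7)$p,
                   mantel_test(d, d2, n_perm = 99, seed = 7)$p)
})

test_that("environmental distances are absolute pairwise differences", {
  v <- c(a = 10, b = 12, c = NA, d = 15)
  ed <- env_distance(v)
  m <- as.matrix(ed)
  expect_equal(dim(m), c(3, 3))
  expect_equal(m["a", "b"], 2)
  expect_equal(m["a", "d"], 5)
})
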