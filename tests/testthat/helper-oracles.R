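# Independent brute-force oracles used to validate the clustering path.
# These deliberately re-derive everything from first principles (naive O(n^3)
# linkage, union-find cutting) and share no code with the implementation.

# naive agglomerative average linkage: scan all active pairs each step
naive_linkage <- function(D, method = c("UPGMA", "WPGMA")) {
  method <- match.arg(method)
  dd <- as.matrix(D)
  n <- nrow(dd)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  coph <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    bmin <- Inf
    k <- length(active)
    for (ii in 1:(k - 1)) for (jj in (ii + 1):k) {
      a <- active[ii]; b <- active[jj]
      if (dd[a, b] < bmin) { bmin <- dd[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    heights[step] <- bmin
    coph[members[[a]], members[[b]]] <- bmin
    coph[members[[b]], members[[a]]] <- bmin
    for (c_ in setdiff(active, c(a, b))) {
      dd[a, c_] <- dd[c_, a] <- if (method == "UPGMA")
        (sizes[a] * dd[a, c_] + sizes[b] * dd[b, c_]) / (sizes[a] + sizes[b])
      else (dd[a, c_] + dd[b, c_]) / 2
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  list(heights = heights, coph = coph)
}

# cut an hclust's merge list at height h by union-find (independent of cutree)
uf_cut <- function(hc, h) {
  n <- length(hc$order)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_members <- vector("list", nrow(hc$merge))
  # heights are monotone for average linkage, so when a merge is at or below
  # h its whole subtree is already united and any member leaf is a valid
  # union-find representative
  for (m in seq_len(nrow(hc$merge))) {
    l <- hc$merge[m, 1]; r <- hc$merge[m, 2]
    lm <- if (l < 0) -l else node_members[[l]]
    rm_ <- if (r < 0) -r else node_members[[r]]
    node_members[[m]] <- c(lm, rm_)
    if (hc$height[m] <= h) {
      ra <- find(lm[1]); rb <- find(rm_[1])
      parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}

# exhaustive scan of the cut-off constraint curves over all merge heights
scan_cutoffs <- function(hc, min_size, min_large, coverage) {
  n <- length(hc$order)
  hs <- sort(unique(hc$height))
  upper <- NA_real_
  lower <- NA_real_
  for (h in hs) {
    sizes <- table(uf_cut(hc, h))
    large <- sizes[sizes >= min_size]
    if (length(large) >= min_large) upper <- max(upper, h, na.rm = TRUE)
    if (sum(large) / n >= coverage) lower <- min(lower, h, na.rm = TRUE)
  }
  list(lower = lower, upper = upper)
}

# symmetric random dissimilarity matrix with unique (tie-free) entries
random_dissimilarity <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 1)
  m <- m + t(m)
  rownames(m) <- colnames(m) <- paste0("L", seq_len(n))
  stats::as.dist(m)
}

# check every triple of a matrix for the ultrametric inequality
is_ultrametric <- function(m, tol = 1e-8) {
  n <- nrow(m)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    trip <- c(m[i, j], m[i, k], m[j, k])
    if (max(trip) > sort(trip, decreasing = TRUE)[2] + tol) return(FALSE)
  }
  TRUE
}
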