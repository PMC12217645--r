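#' Simpson (turnover) dissimilarity between two taxon sets
#'
#' The turnover component of the Sorensen-Dice coefficient,
#' `beta_sim = min(b, c) / (a + min(b, c))`, where `a` is the number of
#' shared taxa and `b`, `c` the numbers unique to each set. Insensitive to
#' richness differences: the value is 0 whenever one set nests inside the
#' other, and 1 for disjoint non-empty sets.
#'
#' @param a_set,b_set character vectors (taxon names); duplicates ignored.
#' @return dissimilarity in `[0, 1]`; `NA` with a warning if either set is
#'   empty (the index is undefined there).
#' @export
#' @examples
#' simpson_pair(c("a", "b", "c"), c("b", "c", "d", "e")) # 1/3
simpson_pair <- function(a_set, b_set) {
  a_set <- unique(a_set)
  b_set <- unique(b_set)
  if (length(a_set) == 0 || length(b_set) == 0) {
    warning("Simpson dissimilarity undefined for an empty taxon set")
    return(NA_real_)
  }
  a <- length(intersect(a_set, b_set))
  b <- length(a_set) - a
  cc <- length(b_set) - a
  m <- min(b, cc)
  if (a + m == 0) return(0) # identical single sets: nested
  m / (a + m)
}

#' Pairwise Simpson dissimilarity matrix
#'
#' Computes `beta_sim` for every unordered pair of cells of an incidence
#' matrix. Cells with zero taxa are excluded beforehand (logged in the
#' `excluded_empty` attribute) because the index is undefined for them.
#'
#' @param incidence an [build_incidence()] object, or a binary matrix with
#'   rownames = cell ids and colnames = taxa.
#' @return a `dist` object with `Labels` = retained cell ids and attributes
#'   `rank` (if known) and `excluded_empty`.
#' @export
simpson_matrix <- function(incidence) {
  rank <- NULL
  if (inherits(incidence, "incidence_matrix")) {
    rank <- incidence$rank
    m <- incidence$values
  } else m <- as.matrix(incidence)
  storage.mode(m) <- "double"
  m <- (m > 0) * 1
  rich <- rowSums(m)
  empty <- rownames(m)[rich == 0]
  if (length(empty)) {
    m <- m[rich > 0, , drop = FALSE]
    rich <- rich[rich > 0]
  }
  n <- nrow(m)
  if (n < 2) fail("need at least 2 non-empty cells")
  a <- tcrossprod(m)                  # shared taxa
  b <- matrix(rich, n, n) - a         # unique to row cell
  cc <- t(b)                          # unique to col cell
  mn <- pmin(b, cc)
  v <- mn / (a + mn)
  v[a + mn == 0] <- 0
  diag(v) <- 0
  d <- stats::as.dist(v)
  attr(d, "rank") <- rank
  attr(d, "excluded_empty") <- empty
  d
}

#' Apply the cell-exclusion rules to a dissimilarity matrix
#'
#' Drops (1) cells with fewer than `min_records` occurrence records (the
#' ordination-path rule) and then (2) cells whose row-mean dissimilarity is
#' extreme (`> mean_max` or `< mean_min`), which flags potentially erroneous
#' outlier cells. The two stages are logged separately.
#'
#' @param d a `dist` of cell dissimilarities.
#' @param record_counts named numeric vector of per-cell record tallies
#'   (names = cell ids); `NULL` skips the record-count stage.
#' @param min_records minimum records per cell (default 10).
#' @param mean_min,mean_max row-mean bounds (defaults 0.01 and 0.99).
#' @return the reduced `dist`, with attribute `exclusions` = list
#'   (`low_records`, `extreme_mean`).
#' @export
exclude_cells <- function(d, record_counts = NULL, min_records = 10,
                          mean_min = 0.01, mean_max = 0.99) {
  m <- as.matrix(d)
  ids <- rownames(m)
  low <- character(0)
  if (!is.null(record_counts)) {
    counts <- record_counts[ids]
    counts[is.na(counts)] <- 0
    low <- ids[counts < min_records]
    keep <- setdiff(ids, low)
    m <- m[keep, keep, drop = FALSE]
  }
  extreme <- character(0)
  if (nrow(m) > 1) {
    rm_ <- (rowSums(m)) / (nrow(m) - 1)
    extreme <- rownames(m)[rm_ > mean_max | rm_ < mean_min]
    keep <- setdiff(rownames(m), extreme)
    m <- m[keep, keep, drop = FALSE]
  }
  if (nrow(m) < 2) fail("all cells excluded (kept %d)", nrow(m))
  out <- stats::as.dist(m)
  attr(out, "rank") <- attr(d, "rank")
  attr(out, "exclusions") <- list(low_records = low, extreme_mean = extreme)
  out
}

#' Write a dissimilarity matrix as CSV
#'
#' @param d a `dist`.
#' @param path output file; square layout with an `id` column.
#' @return `path`, invisibly.
#' @export
write_dist_csv <- function(d, path) {
  m <- as.matrix(d)
  utils::write.csv(data.frame(id = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
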