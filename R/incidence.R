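#' Build a per-rank incidence matrix
#'
#' Constructs the binary cell x taxon presence matrix for one systematic
#' rank. Records identified at a lower rank are rolled up through the
#' taxonomy table (species contribute to their genus and family; genus
#' records to their family); records identified above the target rank are
#' ignored. Rows are restricted to shallow cells when a mask is given.
#'
#' @param records cleaned occurrence data.frame with `scientificName`,
#'   `taxonRank`, `decimalLongitude`, `decimalLatitude`.
#' @param grid an [build_grid()] object.
#' @param rank target rank: `"species"`, `"genus"` or `"family"`.
#' @param taxonomy data.frame with columns `species`, `genus`, `family`
#'   giving the nested classification; `NULL` restricts the matrix to
#'   records identified exactly at `rank`.
#' @param shallow_mask optional character vector of admissible cell ids (see
#'   [shallow_cell_mask()]).
#' @param cells optional pre-computed cell assignment (from
#'   [assign_records()]); computed internally when missing.
#' @return an object of class `incidence_matrix`: list with `rank`, `cells`,
#'   `taxa`, `values` (binary matrix cells x taxa) and `record_counts`
#'   (named per-cell tallies of contributing records).
#' @export
build_incidence <- function(records, grid, rank = c("species", "genus", "family"),
                            taxonomy = NULL, shallow_mask = NULL, cells = NULL) {
  rank <- match.arg(rank)
  if (is.null(cells)) cells <- assign_records(records, grid)
  keep <- !is.na(cells)
  if (!is.null(shallow_mask)) keep <- keep & cells %in% shallow_mask
  rec <- records[keep, , drop = FALSE]
  cell <- cells[keep]

  name <- rollup_names(rec$scientificName, rec$taxonRank, rank, taxonomy)
  ok <- !is.na(name)
  rec <- rec[ok, , drop = FALSE]
  cell <- cell[ok]
  name <- name[ok]
  if (nrow(rec) == 0) fail("no records left at rank '%s'", rank)

  cell_ids <- sort(unique(cell))
  taxa <- sort(unique(name))
  values <- matrix(0L, length(cell_ids), length(taxa),
                   dimnames = list(cell_ids, taxa))
  values[cbind(match(cell, cell_ids), match(name, taxa))] <- 1L
  counts <- table(factor(cell, levels = cell_ids))
  structure(list(rank = rank, cells = cell_ids, taxa = taxa, values = values,
                 record_counts = stats::setNames(as.numeric(counts), cell_ids)),
            class = "incidence_matrix")
}

# map record names to the target rank; NA = record unusable at that rank
rollup_names <- function(names, ranks, target, taxonomy) {
  out <- rep(NA_character_, length(names))
  out[ranks == target] <- names[ranks == target]
  if (is.null(taxonomy)) return(out)
  if (target == "genus") {
    i <- ranks == "species"
    out[i] <- taxonomy$genus[match(names[i], taxonomy$species)]
  } else if (target == "family") {
    i <- ranks == "species"
    out[i] <- taxonomy$family[match(names[i], taxonomy$species)]
    gf <- unique(taxonomy[, c("genus", "family")])
    i <- ranks == "genus"
    out[i] <- gf$family[match(names[i], gf$genus)]
  }
  out
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("Incidence matrix (%s): %d cells x %d taxa, %d presences\n",
              x$rank, length(x$cells), length(x$taxa), sum(x$values)))
  invisible(x)
}

#' Write an incidence matrix as CSV
#'
#' @param incidence an [build_incidence()] object.
#' @param path output file (dense layout, first column `cell`).
#' @param triplet write sparse triplet layout (`cell`, `taxon`, `present`)
#'   instead of dense.
#' @return `path`, invisibly.
#' @export
write_incidence_csv <- function(incidence, path, triplet = FALSE) {
  stopifnot(inherits(incidence, "incidence_matrix"))
  if (triplet) {
    idx <- which(incidence$values == 1L, arr.ind = TRUE)
    utils::write.csv(data.frame(cell = incidence$cells[idx[, 1]],
                                taxon = incidence$taxa[idx[, 2]],
                                present = 1L),
                     path, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(cell = incidence$cells, incidence$values,
                                check.names = FALSE),
                     path, row.names = FALSE)
  }
  invisible(path)
}
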