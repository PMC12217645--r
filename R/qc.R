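#' QC filter configuration
#'
#' Thresholds for the record-level cleaning filters. Defaults follow common
#' practice for large occurrence-database extracts: coordinate uncertainty
#' above 100 km, records older than 1900, a 0.1-degree coastal buffer for
#' shoreline records with imprecise coordinates, and a 200 m depth limit
#' (the shelf break). Records with missing uncertainty or missing year are
#' retained by default (only stated violations are filtered).
#'
#' @param max_uncertainty_km coordinate uncertainty threshold (km).
#' @param min_year earliest admissible collection year.
#' @param buffer_deg coastal buffer in decimal degrees.
#' @param max_depth_m record-level depth limit (m).
#' @param allowed_ranks admissible values of `taxonRank`.
#' @param drop_missing_uncertainty,drop_missing_year treat missing values as
#'   violations (default FALSE).
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(max_uncertainty_km = 100, min_year = 1900,
                      buffer_deg = 0.1, max_depth_m = 200,
                      allowed_ranks = c("species", "genus", "family"),
                      drop_missing_uncertainty = FALSE,
                      drop_missing_year = FALSE) {
  stopifnot(max_uncertainty_km > 0, buffer_deg >= 0, max_depth_m > 0)
  structure(list(max_uncertainty_km = max_uncertainty_km, min_year = min_year,
                 buffer_deg = buffer_deg, max_depth_m = max_depth_m,
                 allowed_ranks = allowed_ranks,
                 drop_missing_uncertainty = drop_missing_uncertainty,
                 drop_missing_year = drop_missing_year),
            class = "qc_config")
}

# fixed filter order: cheap record checks first, spatial checks last
QC_FILTER_ORDER <- c("basis_fossil", "rank_invalid", "coord_invalid",
                     "meridian_equator", "high_uncertainty", "pre_1900",
                     "excluded_taxon", "on_land", "too_deep")

#' Apply the record-level cleaning filters
#'
#' Retains records that are non-fossil, carry an admissible rank, have
#' in-range coordinates not exactly on the prime meridian or equator, have
#' coordinate uncertainty within the threshold, date from `min_year` or
#' later, are not on an exclusion list (pelagic groups, invalid names), lie
#' at sea or within the coastal buffer, and are no deeper than the depth
#' limit. Each removed record is counted under the first failing filter in
#' the fixed order `basis_fossil, rank_invalid, coord_invalid,
#' meridian_equator, high_uncertainty, pre_1900, excluded_taxon, on_land,
#' too_deep`.
#'
#' The land test uses the bathymetry/elevation raster: a record passes if
#' its nearest raster sample is below sea level, or if any below-sea-level
#' sample lies within `buffer_deg` (Chebyshev degrees) of the record. The
#' record-level depth test applies only where `depth` is present; depth for
#' depth-less records is handled at the cell level by
#' [shallow_cell_mask()].
#'
#' @param records occurrence data.frame (Darwin-Core-like headers:
#'   `scientificName`, `taxonRank`, `decimalLongitude`, `decimalLatitude`,
#'   `coordinateUncertaintyInMeters`, `year`, `basisOfRecord`, `depth`).
#' @param bathymetry a [grid_raster()] of elevation (m, negative below sea
#'   level), or `NULL` to skip the land filter.
#' @param exclusion_list character vector of taxon names to exclude.
#' @param config a [qc_config()].
#' @return list with `records` (retained rows) and `report` (a `qc_report`:
#'   `input_count`, `output_count`, `removed` counts per filter).
#' @export
apply_filters <- function(records, bathymetry = NULL,
                          exclusion_list = character(0),
                          config = qc_config()) {
  stopifnot(is.data.frame(records), inherits(config, "qc_config"))
  n <- nrow(records)
  col <- function(nm, default = NA) {
    if (nm %in% names(records)) records[[nm]] else rep(default, n)
  }
  lon <- as.numeric(col("decimalLongitude"))
  lat <- as.numeric(col("decimalLatitude"))
  unc <- as.numeric(col("coordinateUncertaintyInMeters"))
  yr <- as.numeric(col("year"))
  depth <- as.numeric(col("depth"))
  basis <- as.character(col("basisOfRecord", ""))
  rank <- as.character(col("taxonRank", ""))
  name <- as.character(col("scientificName", ""))

  fails <- list(
    basis_fossil = grepl("fossil", basis, ignore.case = TRUE),
    rank_invalid = !(rank %in% config$allowed_ranks),
    coord_invalid = is.na(lon) | is.na(lat) |
      lon < -180 | lon > 180 | lat < -90 | lat > 90,
    meridian_equator = (!is.na(lon) & lon == 0) | (!is.na(lat) & lat == 0),
    high_uncertainty = if (config$drop_missing_uncertainty)
      is.na(unc) | unc > config$max_uncertainty_km * 1000
      else !is.na(unc) & unc > config$max_uncertainty_km * 1000,
    pre_1900 = if (config$drop_missing_year) is.na(yr) | yr < config$min_year
      else !is.na(yr) & yr < config$min_year,
    excluded_taxon = name %in% exclusion_list,
    on_land = rep(FALSE, n),
    too_deep = !is.na(depth) & depth > config$max_depth_m
  )
  # spatial test only for records still alive after the cheap filters
  if (!is.null(bathymetry)) {
    alive <- !Reduce(`|`, fails[c("basis_fossil", "rank_invalid",
                                  "coord_invalid", "meridian_equator",
                                  "high_uncertainty", "pre_1900",
                                  "excluded_taxon")])
    idx <- which(alive)
    if (length(idx))
      fails$on_land[idx] <- is_on_land(bathymetry, lon[idx], lat[idx],
                                       config$buffer_deg)
  }
  removed <- integer(length(QC_FILTER_ORDER))
  names(removed) <- QC_FILTER_ORDER
  attributed <- rep(NA_character_, n)
  dead <- rep(FALSE, n)
  for (f in QC_FILTER_ORDER) {
    hit <- fails[[f]] & !dead
    removed[f] <- sum(hit)
    attributed[hit] <- f
    dead <- dead | fails[[f]]
  }
  out <- records[!dead, , drop = FALSE]
  report <- structure(list(input_count = n, output_count = nrow(out),
                           removed = removed, config = config),
                      class = "qc_report")
  list(records = out, report = report)
}

# TRUE where the point is on land and no ocean raster sample lies within the
# coastal buffer (Chebyshev window in degrees)
is_on_land <- function(bathymetry, lon, lat, buffer_deg) {
  at_sea <- raster_lookup(bathymetry, lon, lat) < 0
  at_sea[is.na(at_sea)] <- FALSE
  land <- !at_sea
  if (!any(land) || buffer_deg <= 0) return(land)
  ocean <- bathymetry$values < 0
  for (i in which(land)) {
    ii <- which(abs(bathymetry$lat - lat[i]) <= buffer_deg + 1e-9)
    jj <- which(abs(bathymetry$lon - lon[i]) <= buffer_deg + 1e-9)
    if (length(ii) && length(jj) && any(ocean[ii, jj], na.rm = TRUE))
      land[i] <- FALSE
  }
  land
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d records in, %d retained (%d removed)\n",
              x$input_count, x$output_count, x$input_count - x$output_count))
  shown <- x$removed[x$removed > 0]
  if (length(shown))
    for (f in names(shown)) cat(sprintf("  %-18s %d\n", f, shown[f]))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report` from [apply_filters()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(list(input_count = report$input_count,
                            output_count = report$output_count,
                            removed = as.list(report$removed)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Collapse duplicate records
#'
#' Records identical on (`scientificName`, longitude and latitude rounded to
#' `precision` decimals, `year`) collapse to the first occurrence.
#'
#' @param records occurrence data.frame.
#' @param precision rounding precision in decimal places (default 4, about
#'   11 m at the equator).
#' @return de-duplicated data.frame.
#' @export
deduplicate_records <- function(records, precision = 4) {
  key <- paste(records$scientificName,
               round(records$decimalLongitude, precision),
               round(records$decimalLatitude, precision),
               records$year, sep = "|")
  records[!duplicated(key), , drop = FALSE]
}

# statuses that remove a name outright (normalised to lower case / spaces)
BAD_TAXON_STATUS <- c("nomen nudum", "nomen dubium", "taxon inquirendum",
                      "uncertain", "non-marine", "non marine")

#' Harmonise taxon names against an accepted-names table
#'
#' Replaces names by their accepted equivalents and removes records whose
#' accepted status marks the name as unusable (nomina nuda, nomina dubia,
#' taxa inquirenda, uncertain, or non-marine). Implemented as a table
#' contract: the caller supplies the synonymy (e.g. exported from a
#' taxonomic backbone); no live service is queried.
#'
#' @param records occurrence data.frame.
#' @param synonym_table data.frame with columns `name`, `accepted_name`,
#'   `accepted_rank`, `status` (`"accepted"` or one of the removal
#'   statuses). May be empty.
#' @param strict remove records whose name is absent from the table
#'   (default FALSE: kept unchanged and logged).
#' @return the harmonised data.frame, with attribute `log` (counts:
#'   `renamed`, `removed_status`, `unmatched`, `removed_unmatched`).
#' @export
harmonize_taxonomy <- function(records, synonym_table = NULL, strict = FALSE) {
  log <- c(renamed = 0L, removed_status = 0L, unmatched = 0L,
           removed_unmatched = 0L)
  if (is.null(synonym_table) || nrow(synonym_table) == 0) {
    attr(records, "log") <- log
    return(records)
  }
  i <- match(records$scientificName, synonym_table$name)
  matched <- !is.na(i)
  status <- tolower(gsub("[_]+", " ", synonym_table$status[i]))
  bad <- matched & status %in% BAD_TAXON_STATUS
  log["removed_status"] <- sum(bad)
  log["unmatched"] <- sum(!matched)
  rename <- matched & !bad
  newname <- synonym_table$accepted_name[i]
  log["renamed"] <- sum(rename & records$scientificName != newname, na.rm = TRUE)
  records$scientificName[rename] <- newname[rename]
  if ("accepted_rank" %in% names(synonym_table)) {
    newrank <- synonym_table$accepted_rank[i]
    records$taxonRank[rename & !is.na(newrank)] <-
      newrank[rename & !is.na(newrank)]
  }
  keep <- !bad
  if (strict) {
    log["removed_unmatched"] <- sum(!matched)
    keep <- keep & matched
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "log") <- log
  out
}
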