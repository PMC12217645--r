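#' Configuration of a synthetic study system
#'
#' Describes a self-contained synthetic world: a shelf strip of equal-area
#' grid cells hugging a meridional coastline, `n_provinces` biogeographic
#' provinces stacked as latitudinal bands of `cells_per_province` cells,
#' hierarchically nested taxa (species in genera in families) whose thermal
#' niche breadth widens with rank, a latitudinal sea-surface-temperature
#' gradient, negative-binomial sampling effort, and optional injected QC
#' defects with hidden truth labels.
#'
#' Defaults correspond to the validation conditions used throughout the
#' package: 6 provinces x 40 cells of 250 km, 80 species per province with a
#' 2% chance of leaking into a neighbouring province, species/genus/family
#' niche s.d. of 1/5/15 degrees C, and about 50 records per cell.
#'
#' @param n_provinces number of planted provinces.
#' @param cells_per_province cells per province.
#' @param cell_edge_km grid cell edge (km).
#' @param coast_width_cells width of the shelf strip in cells; provinces are
#'   consecutive latitudinal runs of this width.
#' @param n_species_per_province species planted per province.
#' @param genus_grouping_size species per genus (grouped across neighbouring
#'   provinces, so genera span several provinces).
#' @param family_grouping_size genera per family.
#' @param turnover_sharpness probability in `[0, 1]` that a species leaks
#'   into one adjacent province (0 = perfectly sharp boundaries).
#' @param thermal_gradient SST decrease per degree latitude (degrees C).
#' @param sst_equator SST at the equator (degrees C).
#' @param seasonal_amplitude amplitude of the monthly SST cycle (degrees C);
#'   the annual mean equals the base field exactly.
#' @param niche_breadth_by_rank named numeric (`species`, `genus`,
#'   `family`): thermal niche s.d. in degrees C, weakly increasing with
#'   rank.
#' @param records_per_cell mean sampling effort per cell.
#' @param effort_dispersion negative-binomial size parameter of the per-cell
#'   record counts (smaller = more geographically uneven effort).
#' @param rank_id_probs named probabilities that a record is identified to
#'   species/genus/family rank only.
#' @param defect_rates named probabilities of injected defect classes, among
#'   `basis_fossil`, `coord_invalid`, `meridian_equator`,
#'   `high_uncertainty`, `pre_1900`, `excluded_taxon`, `on_land`,
#'   `too_deep`; each record receives at most one defect.
#' @param bathy_res_deg,sst_res_deg raster sample resolutions (degrees).
#' @param seed integer master seed; all randomness flows from it through
#'   per-stage sub-streams.
#' @return a validated list of class `world_config`.
#' @export
world_config <- function(n_provinces = 6, cells_per_province = 40,
                         cell_edge_km = 250, coast_width_cells = 5,
                         n_species_per_province = 80,
                         genus_grouping_size = 4, family_grouping_size = 5,
                         turnover_sharpness = 0.02,
                         thermal_gradient = 0.45, sst_equator = 28,
                         seasonal_amplitude = 2,
                         niche_breadth_by_rank = c(species = 1, genus = 5,
                                                   family = 15),
                         records_per_cell = 50, effort_dispersion = 5,
                         rank_id_probs = c(species = 0.90, genus = 0.07,
                                           family = 0.03),
                         defect_rates = numeric(0),
                         bathy_res_deg = 0.05, sst_res_deg = 0.5,
                         seed = 1) {
  counts <- c(n_provinces = n_provinces, cells_per_province = cells_per_province,
              coast_width_cells = coast_width_cells,
              n_species_per_province = n_species_per_province,
              genus_grouping_size = genus_grouping_size,
              family_grouping_size = family_grouping_size)
  if (n_provinces * cells_per_province == 0)
    fail("world has no cells: n_provinces x cells_per_province must be >= 1")
  if (any(counts < 1)) fail("all counts must be >= 1 (%s)",
                            paste(names(counts)[counts < 1], collapse = ", "))
  if (turnover_sharpness < 0 || turnover_sharpness > 1)
    fail("turnover_sharpness must be a probability in [0, 1]")
  stopifnot(cell_edge_km > 0, thermal_gradient >= 0, records_per_cell > 0,
            effort_dispersion > 0, bathy_res_deg > 0, sst_res_deg > 0)
  nb <- niche_breadth_by_rank[c("species", "genus", "family")]
  if (anyNA(nb)) fail("niche_breadth_by_rank needs species, genus and family")
  if (is.unsorted(nb)) fail("niche breadth must weakly increase from species to family")
  if (any(defect_rates < 0 | defect_rates > 1) || sum(defect_rates) > 1)
    fail("defect_rates must be probabilities with sum <= 1")
  known <- c("basis_fossil", "coord_invalid", "meridian_equator",
             "high_uncertainty", "pre_1900", "excluded_taxon", "on_land",
             "too_deep")
  if (length(defect_rates) && !all(names(defect_rates) %in% known))
    fail("unknown defect class(es): %s",
         paste(setdiff(names(defect_rates), known), collapse = ", "))
  rank_id_probs <- rank_id_probs / sum(rank_id_probs)
  structure(list(n_provinces = n_provinces,
                 cells_per_province = cells_per_province,
                 cell_edge_km = cell_edge_km,
                 coast_width_cells = coast_width_cells,
                 n_species_per_province = n_species_per_province,
                 genus_grouping_size = genus_grouping_size,
                 family_grouping_size = family_grouping_size,
                 turnover_sharpness = turnover_sharpness,
                 thermal_gradient = thermal_gradient,
                 sst_equator = sst_equator,
                 seasonal_amplitude = seasonal_amplitude,
                 niche_breadth_by_rank = nb,
                 records_per_cell = records_per_cell,
                 effort_dispersion = effort_dispersion,
                 rank_id_probs = rank_id_probs,
                 defect_rates = defect_rates,
                 bathy_res_deg = bathy_res_deg, sst_res_deg = sst_res_deg,
                 seed = seed),
            class = "world_config")
}

# names of pelagic molluscan taxa used for the excluded-taxon defect class;
# serves as the exclusion-list contract in tests and examples
PELAGIC_TAXA <- c("Janthina janthina", "Clione limacina", "Fiona pinnata",
                  "Recluzia johnii", "Firoloida desmarestia")

#' Build a synthetic world
#'
#' Deterministically (per seed) lays out the shelf strip, plants the
#' provinces, generates monthly SST and bathymetry rasters, creates the
#' nested taxon pool with thermal optima drawn from each species' province,
#' and draws the species x cell occupancy: a species occupies a cell of its
#' province (or, on a leak event, one adjacent province) with probability
#' given by a Gaussian kernel of the cell SST around its optimum. This
#' produces the intended rank contrast: species turn over sharply at
#' province boundaries, while genera and families (grouped across provinces
#' and thermally broader) grade smoothly.
#'
#' @param config a [world_config()].
#' @return an object of class `synthetic_world`: list with `config`, `grid`,
#'   `cells` (labelled shelf cell ids), `province` (named integer truth
#'   labels), `taxa` (species/genus/family table with optima), `occupancy`
#'   (logical species x cell matrix), `cell_sst` (named annual-mean SST per
#'   cell), `sst_monthly` (12 [grid_raster()]s), `sst_annual`, `bathymetry`,
#'   `pelagic_taxa`, and `truth` (planted partition and taxon table).
#' @export
build_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(derive_seed(config$seed, "world"))
  e <- config$cell_edge_km
  K <- config$n_provinces
  M <- config$cells_per_province
  w <- config$coast_width_cells
  n_cells <- K * M
  n_rows <- ceiling(n_cells / w)
  y_span_max <- 2 * EARTH_RADIUS_KM / cos(30 * pi / 180)
  if (n_rows * e > y_span_max)
    fail(paste0("world does not fit on the sphere: %d rows of %g km exceed ",
                "the pole-to-pole span; widen coast_width_cells"), n_rows, e)
  row0 <- -floor(n_rows / 2)
  rows <- row0:(row0 + n_rows - 1)
  cols <- 0:(w - 1)

  lo <- behrmann_unproject(0 + 1e-6, row0 * e + 1e-6)
  hi <- behrmann_unproject(w * e - 1e-6, (row0 + n_rows) * e - 1e-6)
  grid <- build_grid(e, c(lo$lon, hi$lon, lo$lat, hi$lat))

  # serpentine path south -> north; provinces are consecutive runs of M cells
  path <- do.call(rbind, lapply(seq_along(rows), function(i) {
    cc <- if (i %% 2 == 1) cols else rev(cols)
    data.frame(row = rows[i], col = cc)
  }))
  path <- path[seq_len(n_cells), , drop = FALSE]
  cell_ids <- sprintf("r%d_c%d", path$row, path$col)
  province <- stats::setNames(rep(seq_len(K), each = M), cell_ids)

  idx <- match(cell_ids, grid$cells$cell)
  cell_lat <- grid$cells$lat[idx]
  sst_base <- function(lat) config$sst_equator - config$thermal_gradient * abs(lat)
  cell_sst <- stats::setNames(sst_base(cell_lat), cell_ids)

  # rasters: bathymetry fine (drives the land/buffer filter), SST coarser
  pad <- 3
  b_lon <- seq(lo$lon - pad, hi$lon + pad, by = config$bathy_res_deg)
  b_lat <- seq(max(lo$lat - pad, -89.9), min(hi$lat + pad, 89.9),
               by = config$bathy_res_deg)
  bp <- behrmann_project(rep(b_lon, each = 1), rep(0, length(b_lon)))
  x_of_lon <- bp$x
  y_of_lat <- behrmann_project(rep(0, length(b_lat)), b_lat)$y
  col_idx <- floor(x_of_lon / e)
  row_idx <- floor(y_of_lat / e)
  labelled <- matrix(FALSE, n_rows, w,
                     dimnames = list(as.character(rows), as.character(cols)))
  labelled[cbind(match(path$row, rows), match(path$col, cols))] <- TRUE
  in_rows <- row_idx >= row0 & row_idx <= max(rows)
  in_cols <- col_idx >= 0 & col_idx < w
  elev <- matrix(-4000, length(b_lat), length(b_lon))
  land <- x_of_lon >= w * e
  elev[, land] <- 200
  shelf_cols <- which(in_cols)
  for (j in shelf_cols) {
    ri <- row_idx[in_rows]
    on_shelf <- labelled[cbind(match(ri, rows), rep(match(col_idx[j], cols),
                                                    length(ri)))]
    elev[which(in_rows)[on_shelf], j] <- -50
  }
  bathymetry <- grid_raster(b_lon, b_lat, elev)

  s_lon <- seq(lo$lon - pad, hi$lon + pad, by = config$sst_res_deg)
  s_lat <- seq(max(lo$lat - pad, -89.9), min(hi$lat + pad, 89.9),
               by = config$sst_res_deg)
  base_field <- matrix(sst_base(s_lat), length(s_lat), length(s_lon))
  sst_monthly <- lapply(1:12, function(m)
    grid_raster(s_lon, s_lat,
                base_field + config$seasonal_amplitude * cospi(2 * (m - 1) / 12)))
  sst_annual <- grid_raster(s_lon, s_lat, base_field)

  # taxon pool: species ordered by (index within province, province) so that
  # consecutive species in a genus come from neighbouring provinces
  S <- config$n_species_per_province
  ord <- expand.grid(province = seq_len(K), i = seq_len(S),
                     KEEP.OUT.ATTRS = FALSE)
  q <- seq_len(nrow(ord))
  gid <- ceiling(q / config$genus_grouping_size)
  fid <- ceiling(gid / config$family_grouping_size)
  prov_sst <- split(cell_sst, province)
  opt <- vapply(seq_len(nrow(ord)), function(k) {
    r <- range(prov_sst[[ord$province[k]]])
    stats::runif(1, r[1], r[2])
  }, numeric(1))
  taxa <- data.frame(
    species = sprintf("Genus%03d sp%04d", gid, q),
    genus = sprintf("Genus%03d", gid),
    family = sprintf("Family%02d", fid),
    province = ord$province,
    optimum = opt,
    stringsAsFactors = FALSE
  )

  # occupancy: province-truncated Gaussian thermal filtering with rare leaks
  sd_sp <- config$niche_breadth_by_rank[["species"]]
  prov_cells <- split(cell_ids, province)
  occupancy <- matrix(FALSE, nrow(taxa), n_cells,
                      dimnames = list(taxa$species, cell_ids))
  leak <- stats::runif(nrow(taxa)) < config$turnover_sharpness
  leak_dir <- sample(c(-1L, 1L), nrow(taxa), replace = TRUE)
  for (k in seq_len(nrow(taxa))) {
    p <- taxa$province[k]
    cand <- prov_cells[[p]]
    if (leak[k]) {
      p2 <- p + leak_dir[k]
      if (p2 < 1 || p2 > K) p2 <- p - leak_dir[k]
      if (p2 >= 1 && p2 <= K && p2 != p) cand <- c(cand, prov_cells[[p2]])
    }
    pr <- exp(-0.5 * ((cell_sst[cand] - taxa$optimum[k]) / sd_sp)^2)
    hit <- stats::runif(length(cand)) < pr
    if (!any(hit)) hit[which.max(pr[seq_along(prov_cells[[p]])])] <- TRUE
    occupancy[k, cand[hit]] <- TRUE
  }
  # every cell must host at least one species
  empty <- which(colSums(occupancy) == 0)
  for (j in empty) {
    own <- which(taxa$province == province[j])
    best <- own[which.min(abs(taxa$optimum[own] - cell_sst[j]))]
    occupancy[best, j] <- TRUE
  }

  structure(list(config = config, grid = grid, cells = cell_ids,
                 province = province, taxa = taxa, occupancy = occupancy,
                 cell_sst = cell_sst, sst_monthly = sst_monthly,
                 sst_annual = sst_annual, bathymetry = bathymetry,
                 pelagic_taxa = PELAGIC_TAXA,
                 truth = list(province = province, taxa = taxa)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic world: %d provinces x %d cells (%g km edge), %d species\n",
              cfg$n_provinces, cfg$cells_per_province, cfg$cell_edge_km,
              nrow(x$taxa)))
  cat(sprintf("  SST %g to %g C across |lat| %g to %g\n",
              min(x$cell_sst), max(x$cell_sst), 0, max(abs(x$grid$cells$lat))))
  invisible(x)
}

#' Sample occurrence records from a synthetic world
#'
#' Draws per-cell record counts from a negative-binomial effort model, picks
#' for each record a taxon present (species rank) or thermally plausible
#' (genus/family rank, Gaussian weight with the rank's niche s.d.), places
#' it uniformly within its cell, fills Darwin-Core-like fields, and injects
#' the configured defect classes — at most one per record, tagged in the
#' hidden `truth_defect` column so filter fidelity can be audited exactly.
#'
#' @param world a [build_world()] object.
#' @param config a [world_config()]; defaults to the world's own.
#' @return a data.frame with columns `scientificName`, `taxonRank`,
#'   `decimalLongitude`, `decimalLatitude`,
#'   `coordinateUncertaintyInMeters`, `year`, `basisOfRecord`, `depth`,
#'   `source`, and hidden truth columns `truth_defect` (`NA` = clean),
#'   `truth_cell`, `truth_province`.
#' @export
sample_occurrences <- function(world, config = world$config) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(derive_seed(config$seed, "occurrences"))
  cells <- world$cells
  n_cells <- length(cells)
  counts <- stats::rnbinom(n_cells, size = config$effort_dispersion,
                           mu = config$records_per_cell)
  cell <- rep(cells, counts)
  n <- length(cell)
  if (n == 0)
    return(empty_occurrence_table())

  rank <- sample(names(config$rank_id_probs), n, replace = TRUE,
                 prob = config$rank_id_probs)
  name <- character(n)

  # species records: uniform draw among species present in the cell
  occ_by_cell <- lapply(stats::setNames(seq_len(ncol(world$occupancy)), cells),
                        function(j) which(world$occupancy[, j]))
  sp_idx <- which(rank == "species")
  for (grp in split(sp_idx, cell[sp_idx])) {
    present <- occ_by_cell[[cell[grp[1]]]]
    name[grp] <- world$taxa$species[present[sample.int(length(present),
                                                       length(grp),
                                                       replace = TRUE)]]
  }
  # genus/family records: thermal-match weights with the rank's niche sd
  for (rk in c("genus", "family")) {
    ri <- which(rank == rk)
    if (!length(ri)) next
    opt_by <- tapply(world$taxa$optimum, world$taxa[[rk]], mean)
    tab <- data.frame(taxon = names(opt_by), optimum = as.numeric(opt_by),
                      stringsAsFactors = FALSE)
    sdr <- config$niche_breadth_by_rank[[rk]]
    wts <- outer(tab$optimum, world$cell_sst, function(o, t)
      exp(-0.5 * ((t - o) / sdr)^2))
    colnames(wts) <- cells
    for (grp in split(ri, cell[ri])) {
      wv <- wts[, cell[grp[1]]]
      name[grp] <- tab$taxon[sample.int(nrow(tab), length(grp),
                                        replace = TRUE, prob = wv)]
    }
  }

  ci <- match(cell, world$grid$cells$cell)
  gx <- stats::runif(n, world$grid$cells$x0[ci], world$grid$cells$x1[ci])
  gy <- stats::runif(n, world$grid$cells$y0[ci], world$grid$cells$y1[ci])
  pos <- behrmann_unproject(gx, gy)

  rec <- data.frame(
    scientificName = name,
    taxonRank = rank,
    decimalLongitude = pos$lon,
    decimalLatitude = pos$lat,
    coordinateUncertaintyInMeters = round(stats::runif(n, 100, 50000)),
    year = sample(1950:2020, n, replace = TRUE),
    basisOfRecord = "PreservedSpecimen",
    depth = round(stats::runif(n, 1, 100), 1),
    source = "synthetic",
    truth_defect = NA_character_,
    truth_cell = cell,
    truth_province = as.integer(world$province[cell]),
    stringsAsFactors = FALSE
  )

  rates <- config$defect_rates
  if (length(rates) && sum(rates) > 0) {
    classes <- sample(c(names(rates), "none"), n, replace = TRUE,
                      prob = c(rates, 1 - sum(rates)))
    rec$truth_defect <- ifelse(classes == "none", NA_character_, classes)
    strip_lon_max <- max(world$grid$cells$lon) +
      (world$grid$edge_km / 2) / (111.195 * cos(30 * pi / 180))
    for (cls in names(rates)) {
      i <- which(classes == cls)
      if (!length(i)) next
      switch(cls,
        basis_fossil = { rec$basisOfRecord[i] <- "FossilSpecimen" },
        coord_invalid = {
          miss <- stats::runif(length(i)) < 0.5
          rec$decimalLongitude[i[miss]] <- NA_real_
          rec$decimalLatitude[i[!miss]] <- 91 + stats::runif(sum(!miss), 0, 30)
        },
        meridian_equator = {
          on_eq <- stats::runif(length(i)) < 0.5
          rec$decimalLatitude[i[on_eq]] <- 0
          rec$decimalLongitude[i[!on_eq]] <- 0
        },
        high_uncertainty = {
          rec$coordinateUncertaintyInMeters[i] <-
            round(stats::runif(length(i), 100001, 1e6))
        },
        pre_1900 = { rec$year[i] <- sample(1700:1899, length(i), replace = TRUE) },
        excluded_taxon = {
          rec$scientificName[i] <- sample(world$pelagic_taxa, length(i),
                                          replace = TRUE)
          rec$taxonRank[i] <- "species"
        },
        on_land = {
          # deep inland: at least 1 degree east of the coastline
          rec$decimalLongitude[i] <- strip_lon_max +
            stats::runif(length(i), 1, 2)
        },
        too_deep = { rec$depth[i] <- round(stats::runif(length(i), 300, 3000), 1) }
      )
    }
  }
  rownames(rec) <- NULL
  rec
}

empty_occurrence_table <- function() {
  data.frame(scientificName = character(0), taxonRank = character(0),
             decimalLongitude = numeric(0), decimalLatitude = numeric(0),
             coordinateUncertaintyInMeters = numeric(0), year = integer(0),
             basisOfRecord = character(0), depth = numeric(0),
             source = character(0), truth_defect = character(0),
             truth_cell = character(0), truth_province = integer(0),
             stringsAsFactors = FALSE)
}

#' Write / read occurrence tables as Darwin-Core-like CSV
#'
#' Hidden truth columns (`truth_*`) are dropped on write unless
#' `keep_truth = TRUE`.
#'
#' @param records occurrence data.frame.
#' @param path file path.
#' @param keep_truth keep the generator's hidden truth columns.
#' @return `write_occurrences` returns `path` invisibly; `read_occurrences`
#'   returns the data.frame.
#' @export
write_occurrences <- function(records, path, keep_truth = FALSE) {
  if (!keep_truth)
    records <- records[, !grepl("^truth_", names(records)), drop = FALSE]
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}
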