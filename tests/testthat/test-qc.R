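# one hand-built valid record, fields overridable per test
base_record <- function(...) {
  rec <- data.frame(scientificName = "Genus001 sp0001", taxonRank = "species",
                    decimalLongitude = 2.3, decimalLatitude = 1.7,
                    coordinateUncertaintyInMeters = 500, year = 2001,
                    basisOfRecord = "PreservedSpecimen", depth = 20,
                    source = "test", stringsAsFactors = FALSE)
  for (nm in names(list(...))) rec[[nm]] <- list(...)[[nm]]
  rec
}

test_that("single-filter violations are attributed to the right filter", {
  cases <- list(
    list(rec = base_record(year = 1899), filter = "pre_1900"),
    list(rec = base_record(basisOfRecord = "FossilSpecimen"),
         filter = "basis_fossil"),
    list(rec = base_record(taxonRank = "subspecies"), filter = "rank_invalid"),
    list(rec = base_record(decimalLatitude = 0), filter = "meridian_equator"),
    list(rec = base_record(decimalLongitude = 0), filter = "meridian_equator"),
    list(rec = base_record(decimalLatitude = 95), filter = "coord_invalid"),
    list(rec = base_record(decimalLongitude = NA_real_),
         filter = "coord_invalid"),
    list(rec = base_record(coordinateUncertaintyInMeters = 150000),
         filter = "high_uncertainty"),
    list(rec = base_record(depth = 450), filter = "too_deep")
  )
  for (cs in cases) {
    res <- apply_filters(cs$rec)
    expect_equal(res$report$output_count, 0)
    expect_equal(unname(res$report$removed[cs$filter]), 1L,
                 label = cs$filter)
    expect_equal(sum(res$report$removed), 1L)
  }
  # boundary record exactly at 100 km uncertainty is retained
  expect_equal(apply_filters(base_record(
    coordinateUncertaintyInMeters = 100000))$report$output_count, 1)
  # missing uncertainty and missing year retained under default policy
  expect_equal(apply_filters(base_record(
    coordinateUncertaintyInMeters = NA_real_, year = NA))$report$output_count, 1)
})

test_that("a record failing several filters counts once, at the first", {
  rec <- base_record(basisOfRecord = "FossilSpecimen", year = 1850,
                     coordinateUncertaintyInMeters = 2e6)
  res <- apply_filters(rec)
  expect_equal(unname(res$report$removed["basis_fossil"]), 1L)
  expect_equal(sum(res$report$removed), 1L)
})

test_that("coastal buffer admits near-shore points, rejects inland ones", {
  # ocean west of lon 0, land east; samples every 0.05 degrees
  lon <- seq(-2, 2, 0.05)
  lat <- seq(-1, 1, 0.05)
  elev <- outer(lat, lon, function(la, lo) ifelse(lo < 0, -50, 100))
  bathy <- grid_raster(lon, lat, elev)
  at_sea <- base_record(decimalLongitude = -1, decimalLatitude = 0.5)
  # 0.03 deg inland: within the 0.1-deg buffer of the nearest ocean sample
  near_shore <- base_record(decimalLongitude = 0.03, decimalLatitude = 0.5)
  inland <- base_record(decimalLongitude = 1.5, decimalLatitude = 0.5)
  recs <- rbind(at_sea, near_shore, inland)
  res <- apply_filters(recs, bathymetry = bathy)
  expect_equal(res$report$output_count, 2)
  expect_equal(unname(res$report$removed["on_land"]), 1L)
})

test_that("filtering is idempotent, order-insensitive and conserving", {
  w <- tiny_world(seed = 21, defect_rates = c(pre_1900 = 0.05, on_land = 0.05,
                                              too_deep = 0.05))
  occ <- sample_occurrences(w)
  res1 <- apply_filters(occ, bathymetry = w$bathymetry,
                        exclusion_list = w$pelagic_taxa)
  # conservation: removals + retained = input
  expect_equal(res1$report$input_count,
               res1$report$output_count + sum(res1$report$removed))
  # idempotence
  res2 <- apply_filters(res1$records, bathymetry = w$bathymetry,
                        exclusion_list = w$pelagic_taxa)
  expect_equal(res2$report$output_count, res1$report$output_count)
  expect_true(all(res2$report$removed == 0))
  # shuffling rows changes neither the retained set nor the counts
  set.seed(1)
  shuf <- occ[sample(nrow(occ)), , drop = FALSE]
  res3 <- apply_filters(shuf, bathymetry = w$bathymetry,
                        exclusion_list = w$pelagic_taxa)
  expect_equal(res3$report$removed, res1$report$removed)
  expect_setequal(
    paste(res3$records$scientificName, res3$records$decimalLongitude),
    paste(res1$records$scientificName, res1$records$decimalLongitude))
})

test_that("deduplication collapses rounded coordinate/name/year matches", {
  a <- base_record()
  expect_equal(nrow(deduplicate_records(rbind(a, a))), 1)
  # beyond rounding precision: both kept
  b <- base_record(decimalLongitude = 2.3006)
  expect_equal(nrow(deduplicate_records(rbind(a, b), precision = 4)), 2)
  expect_equal(nrow(deduplicate_records(rbind(a, b), precision = 2)), 1)
  # three duplicate pairs -> input - 3
  tab <- rbind(a, a, b, b, base_record(year = 1999), base_record(year = 1999),
               base_record(scientificName = "Other sp"))
  expect_equal(nrow(deduplicate_records(tab)), nrow(tab) - 3)
})

test_that("taxonomic harmonisation renames, removes bad statuses, logs", {
  recs <- rbind(base_record(scientificName = "Turbo sp-A"),
                base_record(scientificName = "Dubium nomen"),
                base_record(scientificName = "Unknown thing"))
  syn <- data.frame(name = c("Turbo sp-A", "Dubium nomen"),
                    accepted_name = c("Turbo A", "Dubium nomen"),
                    accepted_rank = c("species", "species"),
                    status = c("accepted", "nomen dubium"),
                    stringsAsFactors = FALSE)
  out <- harmonize_taxonomy(recs, syn)
  expect_setequal(out$scientificName, c("Turbo A", "Unknown thing"))
  log <- attr(out, "log")
  expect_equal(unname(log["renamed"]), 1L)
  expect_equal(unname(log["removed_status"]), 1L)
  expect_equal(unname(log["unmatched"]), 1L)
  # strict mode removes unmatched names as well
  strict <- harmonize_taxonomy(recs, syn, strict = TRUE)
  expect_equal(strict$scientificName, "Turbo A")
  # empty table in non-strict mode is the identity
  same <- harmonize_taxonomy(recs, NULL)
  expect_equal(same$scientificName, recs$scientificName)
})

test_that("QC report serialises to JSON with conserved counts", {
  res <- apply_filters(rbind(base_record(), base_record(year = 1800)))
  f <- withr::local_tempfile(fileext = ".json")
  write_qc_report(res$report, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$input_count, 2)
  expect_equal(back$output_count, 1)
  expect_equal(back$removed$pre_1900, 1)
})
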