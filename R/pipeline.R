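#' Default run configuration
#'
#' Resolves a (possibly partial) configuration list against the package
#' defaults, which are the analysis' standard settings: 250 km grid,
#' 100 km uncertainty threshold, year >= 1900, 0.1-degree coastal buffer,
#' 200 m depth limit, minimum cluster size 5, at least 10 large clusters,
#' 95% coverage, 0.04 cut-off interval, nMDS dimensions 2/3/4 for
#' species/genus/family with 100 starts, and 999 Mantel permutations.
#'
#' @param ... named overrides of the defaults (see Details in
#'   [validate_config()]).
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  validate_config(list(...))
}

run_config_defaults <- function() {
  list(
    grid = list(edge_km = 250),
    qc = list(max_uncertainty_km = 100, min_year = 1900, buffer_deg = 0.1,
              max_depth_m = 200),
    ranks = c("species", "genus", "family"),
    clustering = list(method = "auto", min_size = 5, min_large_clusters = 10,
                      coverage = 0.95, interval = 0.04),
    exclusion = list(min_records = 10, mean_min = 0.01, mean_max = 0.99),
    nmds = list(k = c(species = 2, genus = 3, family = 4), n_starts = 100),
    mantel = list(n_perm = 999),
    world = list(),
    seed = 1
  )
}

#' Validate and resolve a run configuration
#'
#' Accepts a named list or the path of a YAML file, fills unset fields with
#' the defaults of [run_config()], and rejects unknown keys and
#' out-of-range values with field-level messages.
#'
#' @param config named list or YAML file path; `NULL` or an empty file
#'   yields the all-defaults configuration.
#' @param lax downgrade unknown keys from an error to a warning.
#' @return a list of class `run_config`.
#' @export
validate_config <- function(config = NULL, lax = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) fail("configuration must be a named list or YAML file")
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    msg <- sprintf("unknown configuration key(s): %s",
                   paste(unknown, collapse = ", "))
    if (lax) warning(msg) else fail("%s", msg)
  }
  merged <- utils::modifyList(defaults, config[intersect(names(config),
                                                         names(defaults))])
  check <- function(ok, field, msg) if (!ok) fail("config field %s: %s", field, msg)
  check(merged$grid$edge_km > 0, "grid.edge_km", "must be positive")
  check(merged$qc$max_uncertainty_km > 0, "qc.max_uncertainty_km",
        "must be positive")
  check(merged$qc$buffer_deg >= 0, "qc.buffer_deg", "must be non-negative")
  check(merged$qc$max_depth_m > 0, "qc.max_depth_m", "must be positive")
  check(all(merged$ranks %in% c("species", "genus", "family")), "ranks",
        "must be among species, genus, family")
  check(merged$clustering$interval > 0, "clustering.interval",
        "must be positive")
  check(merged$clustering$min_size >= 1, "clustering.min_size", "must be >= 1")
  check(merged$clustering$coverage >= 0 && merged$clustering$coverage <= 1,
        "clustering.coverage", "must be in [0, 1]")
  check(all(unlist(merged$nmds$k) >= 1), "nmds.k", "must be >= 1")
  check(merged$nmds$n_starts >= 1, "nmds.n_starts", "must be >= 1")
  check(merged$mantel$n_perm >= 1, "mantel.n_perm", "must be >= 1")
  structure(merged, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Executes the stages simulate -> qc -> grid -> beta -> cluster ->
#' coherence -> ordinate -> env for every configured rank, writing each
#' stage's outputs (CSV/JSON/Newick) and a manifest (stage status, timings,
#' seeds, output hashes) under `out_dir`. When `out_dir` already holds a
#' stage's cached outputs from an identical upstream state, the stage is
#' reused instead of recomputed; deleting an intermediate file forces that
#' stage and everything downstream to re-run. A stage failure is recorded
#' in the manifest and downstream stages are skipped.
#'
#' @param config a [run_config()] (its `world` entry parameterises the
#'   simulated world; `seed` drives all stages).
#' @param out_dir output directory (`NULL`: temporary directory).
#' @return invisibly, a list with `manifest`, `results` (per-rank fits) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  config <- validate_config(unclass(config))
  out_dir <- out_dir %||% tempfile("shelfprov_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  failed <- FALSE
  upstream_fresh <- FALSE

  stage <- function(name, files, fun) {
    if (failed) {
      manifest[[name]] <<- list(stage = name, status = "skipped")
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    cache_file <- file.path(cache_dir, paste0(name, ".rds"))
    paths <- file.path(out_dir, files)
    reused <- !upstream_fresh && file.exists(cache_file) && all(file.exists(paths))
    value <- NULL
    status <- "ok"
    if (reused) {
      value <- readRDS(cache_file)
    } else {
      value <- tryCatch(fun(), error = function(e) e)
      if (inherits(value, "error")) {
        status <- "failed"
        failed <<- TRUE
      } else {
        saveRDS(value, cache_file)
        upstream_fresh <<- TRUE
      }
    }
    manifest[[name]] <<- list(
      stage = name,
      status = if (status == "ok" && reused) "cached" else status,
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.list(files),
      hashes = if (status == "ok")
        as.list(unname(tools::md5sum(paths[file.exists(paths)]))) else list(),
      error = if (status == "failed") conditionMessage(value) else NULL
    )
    if (status == "failed") NULL else value
  }

  wcfg <- do.call(world_config, c(config$world,
                                  list(seed = derive_seed(config$seed, "sim"))))

  sim <- stage("simulate", c("occurrences.csv", "bathymetry.csv"), function() {
    world <- build_world(wcfg)
    occ <- sample_occurrences(world)
    write_occurrences(occ, file.path(out_dir, "occurrences.csv"),
                      keep_truth = TRUE)
    write_raster_csv(world$bathymetry, file.path(out_dir, "bathymetry.csv"))
    list(world = world, occ = occ)
  })

  qc <- stage("qc", c("occurrences_clean.csv", "qc_report.json"), function() {
    cfg <- qc_config(max_uncertainty_km = config$qc$max_uncertainty_km,
                     min_year = config$qc$min_year,
                     buffer_deg = config$qc$buffer_deg,
                     max_depth_m = config$qc$max_depth_m)
    res <- apply_filters(sim$occ, bathymetry = sim$world$bathymetry,
                         exclusion_list = sim$world$pelagic_taxa, config = cfg)
    res$records <- deduplicate_records(res$records)
    write_occurrences(res$records, file.path(out_dir, "occurrences_clean.csv"))
    write_qc_report(res$report, file.path(out_dir, "qc_report.json"))
    res
  })

  gridded <- stage("grid", c("grid.csv", "grid.geojson"), function() {
    grid <- sim$world$grid
    shallow <- shallow_cell_mask(grid, sim$world$bathymetry,
                                 config$qc$max_depth_m)
    utils::write.csv(grid$cells[, c("cell", "row", "col", "lon", "lat")],
                     file.path(out_dir, "grid.csv"), row.names = FALSE)
    write_grid_geojson(grid, file.path(out_dir, "grid.geojson"))
    inc <- lapply(stats::setNames(nm = config$ranks), function(rk)
      build_incidence(qc$records, grid, rk, taxonomy = sim$world$taxa,
                      shallow_mask = shallow))
    for (rk in names(inc))
      write_incidence_csv(inc[[rk]],
                          file.path(out_dir, sprintf("incidence_%s.csv", rk)))
    list(grid = grid, shallow = shallow, incidence = inc)
  })

  beta <- stage("beta", sprintf("simpson_%s.csv", config$ranks), function() {
    lapply(stats::setNames(nm = config$ranks), function(rk) {
      d <- simpson_matrix(gridded$incidence[[rk]])
      write_dist_csv(d, file.path(out_dir, sprintf("simpson_%s.csv", rk)))
      d
    })
  })

  cluster <- stage("cluster", c(sprintf("clusters_%s.csv", config$ranks),
                                sprintf("dendrogram_%s.nwk", config$ranks)),
                   function() {
    lapply(stats::setNames(nm = config$ranks), function(rk) {
      fit <- regionalize(beta[[rk]], grid = gridded$grid,
                         min_size = config$clustering$min_size,
                         min_large_clusters = config$clustering$min_large_clusters,
                         coverage = config$clustering$coverage,
                         interval = config$clustering$interval,
                         method = config$clustering$method)
      write_newick(fit, file.path(out_dir, sprintf("dendrogram_%s.nwk", rk)))
      lab <- fit$solutions[[length(fit$solutions)]]$labels
      utils::write.csv(data.frame(cell = names(lab), cluster = as.integer(lab)),
                       file.path(out_dir, sprintf("clusters_%s.csv", rk)),
                       row.names = FALSE)
      fit
    })
  })

  stage("coherence", sprintf("coherence_%s.csv", config$ranks), function() {
    lapply(stats::setNames(nm = config$ranks), function(rk) {
      rep_ <- cluster[[rk]]$coherence[[length(cluster[[rk]]$coherence)]]
      utils::write.csv(rep_, file.path(out_dir,
                                       sprintf("coherence_%s.csv", rk)),
                       row.names = FALSE)
      rep_
    })
  })

  env <- stage("env", c(sprintf("nmds_%s.csv", config$ranks),
                        "env_summary.json"), function() {
    sst <- aggregate_sst(sim$world$sst_monthly, gridded$grid)
    out <- lapply(stats::setNames(nm = config$ranks), function(rk) {
      inc <- gridded$incidence[[rk]]
      d <- exclude_cells(beta[[rk]], inc$record_counts,
                         min_records = config$exclusion$min_records,
                         mean_min = config$exclusion$mean_min,
                         mean_max = config$exclusion$mean_max)
      k <- unlist(config$nmds$k)[[rk]]
      ord <- nmds(d, k = k, n_starts = config$nmds$n_starts,
                  seed = derive_seed(config$seed, paste0("nmds_", rk)))
      coords <- scale_rotate(ord$points)
      cols <- radial_colors(coords)
      utils::write.csv(data.frame(cell = rownames(coords), coords,
                                  colour = cols),
                       file.path(out_dir, sprintf("nmds_%s.csv", rk)),
                       row.names = FALSE)
      surf <- fit_gam_surface(coords, sst)
      mt <- mantel_test(d, env_distance(sst[labels(d)]),
                        n_perm = config$mantel$n_perm,
                        seed = derive_seed(config$seed, paste0("mantel_", rk)))
      list(ordination = ord, coords = coords, surface = surf, mantel = mt)
    })
    jsonlite::write_json(
      lapply(out, function(r) list(
        stress = r$ordination$stress,
        adjusted_r2 = r$surface$adjusted_r2,
        deviance_explained = r$surface$deviance_explained,
        mantel_r = r$mantel$r, mantel_p = r$mantel$p)),
      file.path(out_dir, "env_summary.json"), auto_unbox = TRUE, digits = NA)
    out
  })

  results <- list(sim = sim, qc = qc, grid = gridded, beta = beta,
                  cluster = cluster, env = env)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unname(manifest), manifest_path, auto_unbox = TRUE,
                       null = "null")
  invisible(list(manifest = manifest, results = results, out_dir = out_dir))
}
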