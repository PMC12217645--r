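# small shared study systems so individual tests stay fast

tiny_config <- function(seed = 1, ...) {
  args <- list(n_provinces = 3, cells_per_province = 10,
               n_species_per_province = 25, coast_width_cells = 5,
               records_per_cell = 40, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(world_config, args)
}

tiny_world <- function(seed = 1, ...) build_world(tiny_config(seed, ...))

# flat-ocean raster covering a lon/lat box (all shelf at -50 m)
flat_shelf_raster <- function(lon = seq(-5, 5, 0.5), lat = seq(-5, 5, 0.5),
                              value = -50) {
  grid_raster(lon, lat, matrix(value, length(lat), length(lon)))
}
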