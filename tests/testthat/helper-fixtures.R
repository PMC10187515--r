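# Shared desk-scale fixtures, built once per test file.

small_config <- function(...) {
  synth_config(nx = 48, ny = 48, agg_factor = 4, n_bins = 24, step_ka = 50,
               switch_ka = 600, n_polygons = 6, polygon_cells = 5, ...)
}

# A minimal region_set-shaped list for geometry tests.
toy_regions <- function(species, prey, eco, altitude) {
  list(species_polygons = species, prey_polygon = prey,
       ecoregion_polygons = eco, altitude = altitude)
}

# Deterministic 2-variable presence/background toy for model tests.
toy_pb <- function(n_bg = 200, n_pr = 60, seed = 1) {
  set.seed(seed)
  bg <- data.frame(t = runif(n_bg, 0, 10), p = runif(n_bg, 0, 5))
  pr <- data.frame(t = rnorm(n_pr, 3, 0.7), p = rnorm(n_pr, 4, 0.4))
  pr$t <- pmin(pmax(pr$t, 0), 10); pr$p <- pmin(pmax(pr$p, 0), 5)
  list(pr = pr, bg = bg)
}

# Random suitability map on a small grid.
random_hsi <- function(nr = 10, nc = 10, seed = 1) {
  set.seed(seed)
  grid_raster(matrix(runif(nr * nc), nr, nc))
}
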