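#' Simulate presence occurrences inside the range polygons
#'
#' Samples cells uniformly without replacement among the grid cells whose
#' centres fall inside any range polygon, at most one point per cell, and
#' places each point at its cell centre. The default of 200 points follows
#' the census-based rule of thumb (about two hundred mature individuals in
#' the wild population).
#'
#' @param regions a [generate_regions()] result (or any list with
#'   `species_polygons`).
#' @param grid a [grid_raster()] defining the sampling geometry.
#' @param n number of occurrences (default 200).
#' @param seed integer seed.
#' @return tibble of class `occurrence_set`: `x`, `y`, `row`, `col`, `cell`
#'   (column-major index), `polygon` (1-based id of the covering polygon).
#' @export
simulate_occurrences <- function(regions, grid, n = 200, seed = 1) {
  stopifnot(inherits(grid, "grid_raster"))
  polys <- regions$species_polygons
  masks <- lapply(polys, polygon_mask, grid = grid)
  any_mask <- Reduce(`|`, masks)
  eligible <- which(any_mask)
  if (n > length(eligible))
    stop(sprintf("capacity error: %d points requested but only %d grid cells intersect the range polygons",
                 n, length(eligible)))
  set.seed(seed)
  chosen <- if (length(eligible) == 1L) eligible else
    sample(eligible, n, replace = FALSE)
  cells <- grid_cells(grid)[chosen, , drop = FALSE]
  # first covering polygon wins for the fold id
  pid <- vapply(chosen, function(cl) {
    which(vapply(masks, function(m) m[cl], logical(1)))[1]
  }, integer(1))
  out <- tibble(x = cells$x, y = cells$y, row = cells$row, col = cells$col,
                cell = chosen, polygon = pid)
  class(out) <- c("occurrence_set", class(out))
  out
}

#' Build the background sampling region
#'
#' The background region is the union of the ecoregions that intersect any
#' range polygon with the prey species' distribution polygon, expressed as a
#' cell mask on the supplied grid.
#'
#' @param regions a [generate_regions()] result.
#' @param grid a [grid_raster()].
#' @return logical matrix (grid dimensions): cells in the background region.
#' @export
build_background_region <- function(regions, grid) {
  stopifnot(inherits(grid, "grid_raster"))
  sp_mask <- polygon_mask(regions$species_polygons, grid)
  eco_masks <- lapply(regions$ecoregion_polygons, polygon_mask, grid = grid)
  keep <- vapply(eco_masks, function(m) any(m & sp_mask), logical(1))
  prey_mask <- polygon_mask(regions$prey_polygon, grid)
  if (!any(keep)) {
    warning("no ecoregion intersects a range polygon; using the prey polygon alone")
    return(prey_mask)
  }
  Reduce(`|`, eco_masks[keep]) | prey_mask
}

#' Simulate background points with inverse-distance weighting
#'
#' Samples cells without replacement inside the background region with
#' probability proportional to `1 / (d + eps)`, where `d` is the distance
#' from the cell centre to the nearest presence point and `eps` is one cell
#' size (regularizing the weight at presence cells). At most one point per
#' cell. When the region holds fewer than `2 * n` cells the sample size is
#' scaled down to half the eligible cells, with a message.
#'
#' @param region logical cell mask from [build_background_region()].
#' @param occ an [simulate_occurrences()] result.
#' @param grid the [grid_raster()] the mask refers to.
#' @param n requested number of background points (default 10000).
#' @param seed integer seed.
#' @return tibble of class `background_set`: `x`, `y`, `row`, `col`, `cell`,
#'   `weight` (unnormalized sampling weight).
#' @export
simulate_background <- function(region, occ, grid, n = 10000, seed = 1) {
  stopifnot(inherits(grid, "grid_raster"), is.matrix(region))
  if (!any(region)) stop("background region has zero cells")
  if (nrow(occ) == 0) stop("occurrence set is empty")
  cells <- grid_cells(grid)
  idx <- which(region)
  n_eff <- min(n, floor(length(idx) / 2))
  if (n_eff < 1L) n_eff <- 1L
  if (n_eff < n)
    message(sprintf("background sample scaled down to %d (half of %d eligible cells)",
                    n_eff, length(idx)))
  px <- cells$x[idx]; py <- cells$y[idx]
  d <- rep(Inf, length(idx))
  for (i in seq_len(nrow(occ)))
    d <- pmin(d, sqrt((px - occ$x[i])^2 + (py - occ$y[i])^2))
  eps <- grid$cell_size
  w <- 1 / (d + eps)
  set.seed(seed)
  chosen_local <- if (length(idx) == 1L) 1L else
    sample(seq_along(idx), n_eff, replace = FALSE, prob = w)
  chosen <- idx[chosen_local]
  out <- tibble(x = cells$x[chosen], y = cells$y[chosen],
                row = cells$row[chosen], col = cells$col[chosen],
                cell = chosen, weight = w[chosen_local])
  class(out) <- c("background_set", class(out))
  out
}
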