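#' Simple polygon utilities
#'
#' Polygons are plain two-column matrices of vertices (x, y), implicitly
#' closed. All region arithmetic in the package is cell-based: a polygon is
#' rasterized to the cells whose centres fall inside it, and unions and
#' intersections are taken on cell masks, consistent with the equal-area
#' grid where area = cell count x cell area.
#'
#' @name polygons
NULL

#' Make a rectangular polygon
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return a 4 x 2 vertex matrix.
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  if (xmax <= xmin || ymax <= ymin) stop("degenerate rectangle")
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Polygon area by the shoelace formula
#' @param poly two-column vertex matrix.
#' @return non-negative area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Cells of a grid covered by a polygon
#'
#' A cell is covered when its centre lies inside the polygon
#' (boundary-inclusive up to the ray-crossing convention of [mgcv::in.out()]).
#'
#' @param poly two-column vertex matrix, or a list of such matrices (their
#'   union is taken).
#' @param grid a [grid_raster()] supplying the geometry.
#' @return logical matrix with the grid's dimensions.
#' @export
polygon_mask <- function(poly, grid) {
  stopifnot(inherits(grid, "grid_raster"))
  cells <- grid_cells(grid)
  pts <- cbind(cells$x, cells$y)
  polys <- if (is.list(poly)) poly else list(poly)
  inside <- rep(FALSE, nrow(pts))
  for (p in polys) {
    bnd <- rbind(p, p[1, , drop = FALSE])
    inside <- inside | mgcv::in.out(bnd, pts)
  }
  matrix(inside, nrow = nrow(grid$values), ncol = ncol(grid$values))
}

#' Polygon centroid (vertex mean of the shoelace centroid)
#' @param poly two-column vertex matrix.
#' @return numeric length-2 centroid (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(seq_len(n)[-1], 1L)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < sqrt(.Machine$double.eps)) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cross) / (6 * a), sum((y + y[j]) * cross) / (6 * a))
}
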