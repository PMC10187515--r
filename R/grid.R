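#' Equal-area grid raster
#'
#' A minimal matrix-backed raster on an abstract equal-area grid. Cell (1, 1)
#' is the lower-left cell; x grows with the column index and y with the row
#' index, so cell centres are at `origin + (index - 0.5) * cell_size`.
#' Missing cells are `NA` in `values`. All areas in this package are cell
#' counts times `cell_size^2`; no map projection is involved.
#'
#' @param values numeric matrix (rows = y, cols = x).
#' @param cell_size positive cell side length (abstract km).
#' @param origin numeric length-2, (x, y) of the lower-left grid corner.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size = 1, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L) stop("`origin` must have length 2")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells, cell_size = %g, origin = (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], %d missing\n",
                min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Cell-centre coordinates of a grid raster
#'
#' @param grid a [grid_raster()].
#' @return tibble with `row`, `col`, `x`, `y`, `value`; one row per cell in
#'   column-major order.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_raster"))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = grid$origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * grid$cell_size,
    y = grid$origin[2] + (rep(seq_len(nr), times = nc) - 0.5) * grid$cell_size,
    value = as.vector(grid$values)
  )
}

#' @export
as_tibble.grid_raster <- function(x, ...) grid_cells(x)

#' Block-mean aggregation of a grid raster
#'
#' Aggregates by an integer factor using the block mean, ignoring missing
#' cells; edge blocks use the mean of the available cells. The output cell
#' size is `factor` times the input's.
#'
#' @param raster a [grid_raster()].
#' @param factor positive integer aggregation factor.
#' @return a coarser [grid_raster()].
#' @export
aggregate_raster <- function(raster, factor) {
  stopifnot(inherits(raster, "grid_raster"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  if (factor > nr || factor > nc)
    stop("aggregation factor exceeds the grid dimensions")
  if (factor == 1L) return(raster)
  nro <- ceiling(nr / factor); nco <- ceiling(nc / factor)
  out <- matrix(NA_real_, nro, nco)
  for (i in seq_len(nro)) {
    rows <- ((i - 1L) * factor + 1L):min(i * factor, nr)
    for (j in seq_len(nco)) {
      cols <- ((j - 1L) * factor + 1L):min(j * factor, nc)
      block <- raster$values[rows, cols]
      if (any(!is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
    }
  }
  grid_raster(out, cell_size = raster$cell_size * factor, origin = raster$origin)
}

#' Stack of named environmental layers
#'
#' A set of [grid_raster()] layers sharing one grid geometry, with a time
#' label (ka before present for hindcasts, a calendar period for forecasts)
#' and an optional scenario key.
#'
#' @param layers named list of [grid_raster()] objects on a common grid.
#' @param time_label time of the stack: ka before present (0 = present) or a
#'   future period label.
#' @param scenario optional named list, e.g. `list(emulator =, ssp =, period =)`.
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(layers, time_label = 0, scenario = NULL) {
  if (!length(layers) || is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("`layers` must be a uniquely named list")
  if (!all(vapply(layers, inherits, logical(1), "grid_raster")))
    stop("all layers must be grid_raster objects")
  d <- dim(layers[[1]]$values)
  same <- vapply(layers, function(l)
    identical(dim(l$values), d) &&
      isTRUE(all.equal(l$cell_size, layers[[1]]$cell_size)), logical(1))
  if (!all(same)) stop("all layers must share the grid geometry")
  structure(list(layers = layers, time_label = time_label, scenario = scenario),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> t = %s; %d layers [%s]; %d x %d cells\n",
              format(x$time_label), length(x$layers),
              paste(names(x$layers), collapse = ", "),
              nrow(x$layers[[1]]$values), ncol(x$layers[[1]]$values)))
  invisible(x)
}

#' Layer values of a stack as a tibble
#'
#' @param stack a [climate_stack()].
#' @param cells optional integer vector of cell indices (column-major) to keep.
#' @return tibble with one column per layer plus `cell`, `row`, `col`, `x`, `y`.
#' @export
stack_values <- function(stack, cells = NULL) {
  stopifnot(inherits(stack, "climate_stack"))
  base <- grid_cells(stack$layers[[1]])
  base$value <- NULL
  base$cell <- seq_len(nrow(base))
  vals <- lapply(stack$layers, function(l) as.vector(l$values))
  out <- dplyr::bind_cols(base, as_tibble(vals))
  if (!is.null(cells)) out <- out[out$cell %in% cells, , drop = FALSE]
  out
}

#' @export
as_tibble.climate_stack <- function(x, ...) stack_values(x)

#' Subset a stack to a set of layers
#' @param stack a [climate_stack()].
#' @param names character vector of layer names to keep.
#' @return a [climate_stack()].
#' @export
stack_subset <- function(stack, names) {
  missing <- setdiff(names, names(stack$layers))
  if (length(missing))
    stop("unknown layer(s): ", paste(missing, collapse = ", "))
  climate_stack(stack$layers[names], time_label = stack$time_label,
                scenario = stack$scenario)
}

#' The hindcast layer set
#'
#' Hindcast projections use the warm/cold-quarter temperature and
#' precipitation summaries plus net primary productivity.
#' @return character vector of the five hindcast layer names.
#' @export
hindcast_layers <- function() c("BIO10", "BIO11", "BIO18", "BIO19", "NPP")

#' @export
autoplot.grid_raster <- function(object, ...) {
  df <- grid_cells(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x (km)", y = "y (km)")
}
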