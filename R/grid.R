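#' Geographic grid specification
#'
#' A `grid_spec` describes a regular lon/lat grid with north-up row order and
#' cell-center registration: column `j` (0-based) has center longitude
#' `origin_lon + (j + 0.5) * cell_size`, row `i` has center latitude
#' `origin_lat - (i + 0.5) * cell_size`, so `origin_lat` is the northern edge
#' and row 0 is the northernmost row.
#'
#' @param origin_lon Western edge of the grid, degrees.
#' @param origin_lat Northern edge of the grid, degrees.
#' @param cell_size Cell edge length, degrees. Default 0.00833 (~1 km).
#' @param n_rows,n_cols Grid dimensions.
#' @param nodata Sentinel value used for masked cells on disk (in memory
#'   masked cells are `NA`).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_lon, origin_lat, cell_size = 0.00833,
                      n_rows, n_cols, nodata = -9999) {
  stopifnot(is.numeric(cell_size), cell_size > 0,
            n_rows >= 1, n_cols >= 1,
            is.finite(origin_lon), is.finite(origin_lat))
  structure(list(origin_lon = as.numeric(origin_lon),
                 origin_lat = as.numeric(origin_lat),
                 cell_size = as.numeric(cell_size),
                 n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 nodata = as.numeric(nodata)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g deg, origin (%.6g, %.6g) [NW corner]\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return `cell_center_lons()`: vector of `n_cols` center longitudes;
#'   `cell_center_lats()`: vector of `n_rows` center latitudes (north to
#'   south).
#' @export
cell_center_lons <- function(grid) {
  grid$origin_lon + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

#' @rdname cell_center_lons
#' @export
cell_center_lats <- function(grid) {
  grid$origin_lat - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

#' Test exact grid compatibility
#'
#' Two grids are compatible for cell-wise arithmetic only if every field
#' matches exactly.
#' @param a,b [grid_spec()] objects.
#' @export
grids_identical <- function(a, b) {
  isTRUE(a$origin_lon == b$origin_lon) && isTRUE(a$origin_lat == b$origin_lat) &&
    isTRUE(a$cell_size == b$cell_size) &&
    isTRUE(a$n_rows == b$n_rows) && isTRUE(a$n_cols == b$n_cols)
}

stop_grid_mismatch <- function() stop("grid mismatch", call. = FALSE)

#' Raster layer on a geographic grid
#'
#' Values are held as an `n_rows x n_cols` numeric matrix in north-up order;
#' masked (nodata) cells are `NA` and propagate strictly through arithmetic:
#' any operation with a masked operand yields a masked cell.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix of dim `c(n_rows, n_cols)`, or a scalar which
#'   is recycled.
#' @param units Free-text unit tag (e.g. `"tCO2/ha"`).
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, units = "") {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("values shape does not match grid (", grid$n_rows, " x ", grid$n_cols, ")",
         call. = FALSE)
  structure(list(grid = grid, values = values, units = units),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_layer> %d x %d [%s], %d masked cells, range [%.6g, %.6g]\n",
              nrow(v), ncol(v), x$units, sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
Ops.raster_layer <- function(e1, e2) {
  if (nargs() == 1L)
    return(raster_layer(e1$grid, get(.Generic)(e1$values), e1$units))
  a <- e1; b <- e2
  if (inherits(a, "raster_layer") && inherits(b, "raster_layer")) {
    if (!grids_identical(a$grid, b$grid)) stop_grid_mismatch()
    raster_layer(a$grid, get(.Generic)(a$values, b$values), a$units)
  } else if (inherits(a, "raster_layer")) {
    raster_layer(a$grid, get(.Generic)(a$values, b), a$units)
  } else {
    raster_layer(b$grid, get(.Generic)(a, b$values), b$units)
  }
}

#' Summaries of unmasked cells
#'
#' `layer_sum()` totals unmasked cell values; `layer_mask()` returns the
#' logical validity matrix (TRUE = unmasked).
#' @param layer A [raster_layer()].
#' @export
layer_sum <- function(layer) sum(layer$values, na.rm = TRUE)

#' @rdname layer_sum
#' @export
layer_mask <- function(layer) !is.na(layer$values)
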