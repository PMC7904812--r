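#' Zone sets (country / region polygons)
#'
#' A `zone_set` is an ordered list of zones, each a polygon (possibly
#' multipart, possibly with holes) tagged with a unique `zone_id` and a
#' `region_id`. Geometry is stored as a list of rings, each a two-column
#' matrix of (lon, lat) vertices; ring membership is evaluated with the
#' even-odd rule, so holes and multipart polygons need no special casing.
#'
#' @param zones List of zones created with [zone()].
#' @return An object of class `zone_set`.
#' @export
zone_set <- function(zones) {
  ids <- vapply(zones, function(z) z$zone_id, "")
  if (anyDuplicated(ids)) stop("zone_ids must be unique", call. = FALSE)
  structure(zones, class = "zone_set")
}

#' @param zone_id,region_id Identifier strings.
#' @param rings List of two-column (lon, lat) vertex matrices.
#' @rdname zone_set
#' @export
zone <- function(zone_id, region_id, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  for (r in rings) stopifnot(is.matrix(r), ncol(r) == 2, nrow(r) >= 3)
  list(zone_id = as.character(zone_id), region_id = as.character(region_id),
       rings = rings)
}

#' Axis-aligned rectangle ring
#'
#' Convenience constructor for rectangular zone/project geometry.
#' @param lon0,lat0,lon1,lat1 Opposite corners, degrees.
#' @export
rect_ring <- function(lon0, lat0, lon1, lat1) {
  cbind(lon = c(lon0, lon1, lon1, lon0),
        lat = c(lat0, lat0, lat1, lat1))
}

# Even-odd (crossing number) point-in-polygon over a list of rings,
# vectorized over points. Points exactly on an edge fall on whichever side
# the crossing test puts them; zone assignment resolves shared borders by
# file order.
points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring)
    jprev <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      xi <- x[k]; yi <- y[k]
      xj <- x[jprev[k]]; yj <- y[jprev[k]]
      if (yi == yj) next
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
  }
  inside
}

ring_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

#' Bilinear resampling onto a target grid
#'
#' Values at target cell centers are bilinear interpolations of the four
#' surrounding source cell centers; interpolation is exact for affine fields.
#' A target cell is masked if its four-point support includes any masked
#' source cell or falls outside the source center lattice. Target centers
#' that coincide with source centers (within 1e-9 cells) return the source
#' value unchanged, so resampling a layer onto its own grid is the identity.
#'
#' @param layer Source [raster_layer()].
#' @param target Target [grid_spec()]; `target$cell_size` must be >= the
#'   source cell size (same-scale or coarsening).
#' @return A [raster_layer()] on `target`.
#' @export
resample_bilinear <- function(layer, target) {
  src <- layer$grid
  if (target$cell_size < src$cell_size - 1e-12)
    stop("target grid is finer than source; only coarsening or same-scale resampling is supported",
         call. = FALSE)
  lon <- cell_center_lons(target)
  lat <- cell_center_lats(target)
  # fractional 0-based source center indices
  fx <- (lon - src$origin_lon) / src$cell_size - 0.5
  fy <- (src$origin_lat - lat) / src$cell_size - 0.5
  snap <- function(f) { r <- round(f); ifelse(abs(f - r) < 1e-9, r, f) }
  fx <- snap(fx); fy <- snap(fy)
  in_x <- fx >= 0 & fx <= src$n_cols - 1L
  in_y <- fy >= 0 & fy <= src$n_rows - 1L
  if (!any(in_x) || !any(in_y)) stop_grid_mismatch()

  # clamp so the rightmost/bottom center uses the last interval with weight 1
  j0 <- pmin(pmax(floor(fx), 0L), src$n_cols - 2L)
  i0 <- pmin(pmax(floor(fy), 0L), src$n_rows - 2L)
  wx <- fx - j0
  wy <- fy - i0
  v <- layer$values
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  # a source cell is part of the support only if its weight is non-zero, so
  # exact node hits are not contaminated by masked neighbours
  term <- function(w, x) ifelse(w == 0, 0, w * x)
  for (i in seq_len(target$n_rows)) {
    if (!in_y[i]) next
    r0 <- i0[i] + 1L; wyi <- wy[i]
    top <- v[r0, ]; bot <- v[r0 + 1L, ]
    jj <- j0 + 1L
    val <- term((1 - wyi) * (1 - wx), top[jj]) +
      term((1 - wyi) * wx, top[jj + 1L]) +
      term(wyi * (1 - wx), bot[jj]) +
      term(wyi * wx, bot[jj + 1L])
    val[!in_x] <- NA_real_
    out[i, ] <- val
  }
  raster_layer(target, out, layer$units)
}

#' Clip a layer to the tropical latitude band
#'
#' Cells whose center latitude falls outside the closed interval
#' `[lat_south, lat_north]` are masked; cells exactly on the boundary are
#' retained.
#'
#' @param layer A [raster_layer()].
#' @param lat_north,lat_south Band limits, degrees (defaults: the tropics,
#'   +/-23.44).
#' @export
clip_tropics <- function(layer, lat_north = 23.44, lat_south = -23.44) {
  lat <- cell_center_lats(layer$grid)
  out <- layer$values
  out[lat < lat_south | lat > lat_north, ] <- NA_real_
  raster_layer(layer$grid, out, layer$units)
}

#' Cell surface area in hectares
#'
#' True latitude-dependent spherical cell area on a sphere of radius
#' 6,371,000 m: `area = R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))`,
#' constant within a row and strictly decreasing with |latitude|. With
#' `constant = TRUE` every cell instead gets the equatorial-row area of the
#' same grid (nominal fixed-area convention).
#'
#' @param grid A [grid_spec()].
#' @param constant Use a constant nominal area for all rows.
#' @return A [raster_layer()] in hectares.
#' @export
cell_area_ha <- function(grid, constant = FALSE) {
  R <- 6371000
  cs_rad <- grid$cell_size * pi / 180
  row_area <- function(lat_center) {
    top <- (lat_center + grid$cell_size / 2) * pi / 180
    bot <- (lat_center - grid$cell_size / 2) * pi / 180
    R^2 * cs_rad * (sin(top) - sin(bot)) / 1e4
  }
  a <- if (constant) rep(row_area(0), grid$n_rows) else row_area(cell_center_lats(grid))
  raster_layer(grid, matrix(a, grid$n_rows, grid$n_cols), "ha")
}

#' Zonal sums by the cell-center rule
#'
#' Sums unmasked cell values whose centers fall inside each zone polygon.
#' A cell on a shared border is assigned to exactly one zone: the first zone
#' in file order that contains it. A zone containing no cell centers gets
#' sum 0 and `empty = TRUE` with a warning.
#'
#' @param layer A [raster_layer()].
#' @param zones A [zone_set()].
#' @return `data.frame(zone_id, region_id, sum, n_cells, empty)`.
#' @export
zonal_sum <- function(layer, zones) {
  g <- layer$grid
  lon <- cell_center_lons(g)
  lat <- cell_center_lats(g)
  px <- rep(lon, each = g$n_rows)
  py <- rep(lat, times = g$n_cols)
  vals <- as.vector(layer$values)
  assigned <- rep(FALSE, length(px))
  out <- data.frame(zone_id = character(0), region_id = character(0),
                    sum = numeric(0), n_cells = integer(0), empty = logical(0))
  for (z in zones) {
    bb <- ring_bbox(z$rings)
    cand <- which(!assigned & px >= bb["xmin"] & px <= bb["xmax"] &
                    py >= bb["ymin"] & py <= bb["ymax"])
    inside <- if (length(cand))
      cand[points_in_rings(px[cand], py[cand], z$rings)] else integer(0)
    assigned[inside] <- TRUE
    n_in <- length(inside)
    if (n_in == 0L)
      warning("zone '", z$zone_id, "' contains no cell centers", call. = FALSE)
    out <- rbind(out, data.frame(
      zone_id = z$zone_id, region_id = z$region_id,
      sum = sum(vals[inside], na.rm = TRUE),
      n_cells = n_in, empty = n_in == 0L))
  }
  out
}
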