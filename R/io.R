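#' Raster I/O: ESRI ASCII grid
#'
#' Single-band plain-text raster exchange in geographic (lon/lat, WGS84)
#' coordinates. Values are written north-up, one row per line, at full
#' double precision (`%.17g`), so write/read round-trips are bit-exact.
#' The header `NODATA_value` is honoured on read (such cells become masked)
#' and emitted on write for masked cells.
#'
#' @param layer A [raster_layer()].
#' @param path File path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(layer, path) {
  g <- layer$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$origin_lon),
    sprintf("yllcorner %.17g", g$origin_lat - g$n_rows * g$cell_size),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", g$nodata)), con)
  v <- layer$values
  v[is.na(v)] <- g$nodata
  for (i in seq_len(g$n_rows))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  invisible(path)
}

#' @param units Unit tag to attach to the layer read.
#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, units = "") {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != n_rows * n_cols)
    stop("malformed ASCII grid: expected ", n_rows * n_cols, " values", call. = FALSE)
  m <- matrix(vals, n_rows, n_cols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  g <- grid_spec(origin_lon = hdr$xllcorner,
                 origin_lat = hdr$yllcorner + n_rows * hdr$cellsize,
                 cell_size = hdr$cellsize, n_rows = n_rows, n_cols = n_cols,
                 nodata = hdr$nodata_value)
  raster_layer(g, m, units)
}

ring_to_geojson <- function(ring) {
  lapply(c(seq_len(nrow(ring)), 1L), function(i) c(ring[i, 1], ring[i, 2]))
}

geojson_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  colnames(m) <- c("lon", "lat")
  m
}

#' Vector I/O: GeoJSON zones and projects
#'
#' Zones are written as a GeoJSON FeatureCollection of Polygon features with
#' `zone_id` and `region_id` properties (each ring of a zone becomes one
#' polygon ring; membership uses the even-odd rule, so multipart zones are
#' supported). Projects use `project_id` instead.
#'
#' @param zones A [zone_set()].
#' @param path File path.
#' @export
write_zones_geojson <- function(zones, path) {
  features <- lapply(zones, function(z) {
    list(type = "Feature",
         properties = list(zone_id = z$zone_id, region_id = z$region_id),
         geometry = list(type = "Polygon",
                         coordinates = lapply(z$rings, ring_to_geojson)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zones_geojson
#' @export
read_zones_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  zone_set(lapply(fc$features, function(f) {
    zone(f$properties$zone_id, f$properties$region_id,
         lapply(f$geometry$coordinates, geojson_to_ring))
  }))
}

#' Project records: geometry plus issued-VCU series
#'
#' @param projects List of [project_record()] objects.
#' @param geojson_path,csv_path Paths for the polygon file and the
#'   `(project_id, vintage_year, vcu_tco2e)` CSV.
#' @export
write_projects <- function(projects, geojson_path, csv_path) {
  features <- lapply(projects, function(p) {
    list(type = "Feature",
         properties = list(project_id = p$project_id),
         geometry = list(type = "Polygon",
                         coordinates = lapply(p$rings, ring_to_geojson)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       geojson_path, auto_unbox = TRUE, digits = NA)
  vcu <- do.call(rbind, lapply(projects, function(p)
    data.frame(project_id = p$project_id,
               vintage_year = p$vcu_series$vintage_year,
               vcu_tco2e = p$vcu_series$vcu_tco2e)))
  utils::write.csv(vcu, csv_path, row.names = FALSE)
  invisible(geojson_path)
}

#' @rdname write_projects
#' @export
read_projects <- function(geojson_path, csv_path) {
  fc <- jsonlite::read_json(geojson_path)
  vcu <- utils::read.csv(csv_path)
  lapply(fc$features, function(f) {
    id <- f$properties$project_id
    s <- vcu[vcu$project_id == id, c("vintage_year", "vcu_tco2e"), drop = FALSE]
    s <- s[order(s$vintage_year), ]
    project_record(id, lapply(f$geometry$coordinates, geojson_to_ring), s)
  })
}

#' A VCS project record
#'
#' @param project_id Identifier.
#' @param rings Polygon rings (list of two-column lon/lat matrices).
#' @param vcu_series `data.frame(vintage_year, vcu_tco2e)`; issued verified
#'   carbon units per vintage, values >= 0, years strictly increasing.
#' @export
project_record <- function(project_id, rings, vcu_series) {
  if (is.matrix(rings)) rings <- list(rings)
  stopifnot(all(vcu_series$vcu_tco2e >= 0),
            !is.unsorted(vcu_series$vintage_year, strictly = TRUE))
  structure(list(project_id = as.character(project_id), rings = rings,
                 vcu_series = vcu_series),
            class = "project_record")
}
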