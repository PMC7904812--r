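#' Certification parameters
#'
#' @param buffer_fraction Share of gross credits withheld against
#'   non-permanence risk (VCS AFOLU baseline 0.20).
#' @param bgc_decay_years Belowground-pool decay horizon, years: each year's
#'   avoided belowground emission is issued in this many equal annual
#'   tranches (credit timing, not reduction).
#' @export
cert_params <- function(buffer_fraction = 0.20, bgc_decay_years = 10) {
  stopifnot(buffer_fraction >= 0, buffer_fraction < 1, bgc_decay_years >= 1)
  structure(list(buffer_fraction = buffer_fraction,
                 bgc_decay_years = as.integer(bgc_decay_years)),
            class = "cert_params")
}

#' Annualize projected deforestation
#'
#' Converts the projected total fraction of forest lost over the projection
#' horizon into a per-year loss rate. The default is simple proration
#' `d_total / horizon_years`; `compound = TRUE` instead uses
#' `1 - (1 - d_total)^(1/horizon)`.
#'
#' @param d_total [raster_layer()] of projected loss fraction in \[0, 1\].
#' @param horizon_years Projection period length, years (default 15).
#' @param compound Use compound annualization.
#' @return [raster_layer()] `d_annual`, fraction per year.
#' @export
annualize_deforestation <- function(d_total, horizon_years = 15,
                                    compound = FALSE) {
  v <- d_total$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("d_total must lie in [0, 1]", call. = FALSE)
  d <- if (compound) 1 - (1 - v)^(1 / horizon_years) else v / horizon_years
  raster_layer(d_total$grid, d, "1/yr")
}

#' VCS eligibility mask
#'
#' A cell is eligible (1) iff its land-cover code is in the eligible set,
#' it is not recently deforested, carries no human settlement, and lies
#' inside the tropical band. Unknown land-cover codes are ineligible.
#'
#' @param landcover [raster_layer()] of integer class codes.
#' @param eligible_codes Vector of certifiable (forest) class codes.
#' @param recent_loss,settlements 0/1 [raster_layer()] exclusion masks.
#' @param lat_north,lat_south Tropical band limits, degrees.
#' @return 0/1 [raster_layer()] (masked cells stay masked).
#' @export
eligibility_mask <- function(landcover, eligible_codes, recent_loss,
                             settlements, lat_north = 23.44,
                             lat_south = -23.44) {
  if (!grids_identical(landcover$grid, recent_loss$grid) ||
      !grids_identical(landcover$grid, settlements$grid)) stop_grid_mismatch()
  ok <- (landcover$values %in% eligible_codes) &
    recent_loss$values == 0 & settlements$values == 0
  m <- matrix(as.numeric(ok), landcover$grid$n_rows, landcover$grid$n_cols)
  m[is.na(landcover$values) | is.na(recent_loss$values) |
      is.na(settlements$values)] <- NA_real_
  clip_tropics(raster_layer(landcover$grid, m, "0/1"),
               lat_north, lat_south)
}

#' Certify pool stocks into investible CO2 flux
#'
#' Applies additionality (the annualized deforestation rate), the
#' non-permanence buffer, and the eligibility mask to the pool stack,
#' producing per-cell annual certifiable flux. Per track:
#' `density_fast = (1 - buffer) * d_annual * (agc + soc)` and
#' `density_slow = (1 - buffer) * d_annual * bgc` (tCO2/ha/yr); per-cell
#' flux is density times cell area times the 0/1 mask (tCO2/yr). The slow
#' component is the belowground pool, whose revenue is ramped over
#' `bgc_decay_years` by the finance stage.
#'
#' @param pools A [build_pool_stack()] result.
#' @param d_annual [raster_layer()], per-year loss fraction in \[0, 1\].
#' @param mask 0/1 eligibility [raster_layer()].
#' @param area Cell-area [raster_layer()], ha (see [cell_area_ha()]).
#' @param params A [cert_params()].
#' @return Object of class `investible_flux` with `flux_fast`, `flux_slow`,
#'   `flux_total` (tCO2/yr per cell) and `density_fast`, `density_slow`
#'   (tCO2/ha/yr), each a low/central/high list; plus `mask`, `area`,
#'   `params`.
#' @export
certify <- function(pools, d_annual, mask, area, params = cert_params()) {
  g <- pools$agc$central$grid
  for (l in list(d_annual, mask, area))
    if (!grids_identical(g, l$grid)) stop_grid_mismatch()
  if (any(d_annual$values < 0 | d_annual$values > 1, na.rm = TRUE))
    stop("d_annual must lie in [0, 1]", call. = FALSE)
  keep <- 1 - params$buffer_fraction
  tracks <- c("low", "central", "high")
  density_fast <- density_slow <- flux_fast <- flux_slow <- flux_total <-
    stats::setNames(vector("list", 3), tracks)
  for (tr in tracks) {
    df <- keep * d_annual$values *
      (pools$agc[[tr]]$values + pools$soc[[tr]]$values)
    ds <- keep * d_annual$values * pools$bgc[[tr]]$values
    density_fast[[tr]] <- raster_layer(g, df, "tCO2/ha/yr")
    density_slow[[tr]] <- raster_layer(g, ds, "tCO2/ha/yr")
    ff <- df * area$values * mask$values
    fs <- ds * area$values * mask$values
    flux_fast[[tr]] <- raster_layer(g, ff, "tCO2/yr")
    flux_slow[[tr]] <- raster_layer(g, fs, "tCO2/yr")
    flux_total[[tr]] <- raster_layer(g, ff + fs, "tCO2/yr")
  }
  structure(list(flux_fast = flux_fast, flux_slow = flux_slow,
                 flux_total = flux_total,
                 density_fast = density_fast, density_slow = density_slow,
                 mask = mask, area = area, params = params),
            class = "investible_flux")
}

#' @export
print.investible_flux <- function(x, ...) {
  cat(sprintf("<investible_flux> buffer %.0f%%, central total %.6g tCO2/yr over eligible cells\n",
              100 * x$params$buffer_fraction, layer_sum(x$flux_total$central)))
  invisible(x)
}
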