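#' Finance parameters for the discounted cash-flow model
#'
#' Defaults reflect typical avoided-deforestation project economics: $25/ha
#' establishment at project start, $10/ha/yr maintenance, a $5.8/tCO2 carbon
#' price held flat for the first five years then appreciating 5%/yr, a
#' 30-year project, and a 10% risk-adjusted discount rate. Maintenance and
#' revenue are booked at end-of-year t = 1..horizon; establishment is paid
#' at t = 0 undiscounted.
#'
#' @param establishment_cost $/ha, one-off at t = 0.
#' @param maintenance_cost $/ha/yr.
#' @param price0 Starting carbon price, $/tCO2.
#' @param flat_years Years the price stays at `price0`.
#' @param appreciation Annual price growth after the flat period.
#' @param horizon Project length, years.
#' @param discount Annual discount rate.
#' @param cost_multiplier Scales both cost lines (scenario analyses).
#' @export
finance_params <- function(establishment_cost = 25, maintenance_cost = 10,
                           price0 = 5.8, flat_years = 5, appreciation = 0.05,
                           horizon = 30, discount = 0.10,
                           cost_multiplier = 1.0) {
  stopifnot(establishment_cost >= 0, maintenance_cost >= 0, price0 >= 0,
            discount > 0, discount < 1, flat_years <= horizon,
            cost_multiplier >= 0)
  structure(list(establishment_cost = establishment_cost,
                 maintenance_cost = maintenance_cost, price0 = price0,
                 flat_years = as.integer(flat_years),
                 appreciation = appreciation, horizon = as.integer(horizon),
                 discount = discount, cost_multiplier = cost_multiplier),
            class = "finance_params")
}

#' Carbon price in project year t
#'
#' `price0` during the flat period, then
#' `price0 * (1 + appreciation)^(t - flat_years)`.
#'
#' @param t Project year(s), 1..horizon.
#' @param params A [finance_params()].
#' @export
price_at_year <- function(t, params = finance_params()) {
  if (any(t < 1 | t > params$horizon)) stop("year out of range", call. = FALSE)
  ifelse(t <= params$flat_years, params$price0,
         params$price0 * (1 + params$appreciation)^(t - params$flat_years))
}

# Belowground tranche ramp: fraction of the slow flux credited in year t.
bgc_ramp <- function(t, cert) pmin(t, cert$bgc_decay_years) / cert$bgc_decay_years

# Present value of $1/yr for n years at rate r (ordinary annuity).
annuity_factor <- function(n, r) (1 - (1 + r)^-n) / r

#' Net present value of a cell's certified flux
#'
#' Year-loop discounted cash-flow engine, vectorized over cells:
#' `NPV = -E*c*A + sum_t [ p(t) * (ff + fs*min(t,D)/D) - M*c*A ] / (1+r)^t`
#' with establishment `E` at t = 0 undiscounted, maintenance `M` and carbon
#' revenue at end of each year, the belowground (slow) flux ramped over the
#' D-year decay window, and cost multiplier `c`.
#'
#' @param flux_fast,flux_slow Certified flux, tCO2/yr (vectors/matrices of
#'   equal shape; fast = aboveground + soil, slow = belowground).
#' @param area_ha Cell area, ha.
#' @param params A [finance_params()].
#' @param cert A [cert_params()] (supplies the decay window).
#' @return NPV in $ per cell, same shape as the inputs.
#' @export
npv_per_cell <- function(flux_fast, flux_slow, area_ha,
                         params = finance_params(), cert = cert_params()) {
  if (any(flux_fast < 0, na.rm = TRUE) || any(flux_slow < 0, na.rm = TRUE))
    stop("negative flux", call. = FALSE)
  cm <- params$cost_multiplier
  npv <- -params$establishment_cost * cm * area_ha
  for (t in seq_len(params$horizon)) {
    cash <- price_at_year(t, params) *
      (flux_fast + flux_slow * bgc_ramp(t, cert)) -
      params$maintenance_cost * cm * area_ha
    npv <- npv + cash / (1 + params$discount)^t
  }
  npv
}

#' Break-even starting carbon price
#'
#' The `price0` at which NPV is exactly zero. Revenue is proportional to
#' `price0` (the whole schedule scales), so the break-even price is the
#' closed-form ratio PV(costs) / PV(revenue at price0 = 1). Cells with zero
#' flux return `Inf` (never viable).
#'
#' @inheritParams npv_per_cell
#' @return Break-even `price0` in $/tCO2, same shape as the inputs.
#' @export
break_even_price0 <- function(flux_fast, flux_slow, area_ha,
                              params = finance_params(),
                              cert = cert_params()) {
  t <- seq_len(params$horizon)
  disc <- (1 + params$discount)^-t
  relprice <- ifelse(t <= params$flat_years, 1,
                     (1 + params$appreciation)^(t - params$flat_years))
  unit_fast <- sum(relprice * disc)
  unit_slow <- sum(relprice * bgc_ramp(t, cert) * disc)
  cm <- params$cost_multiplier
  pv_costs <- cm * area_ha *
    (params$establishment_cost +
       params$maintenance_cost * annuity_factor(params$horizon, params$discount))
  denom <- flux_fast * unit_fast + flux_slow * unit_slow
  out <- pv_costs / denom
  out[denom <= 0] <- Inf
  out
}

#' NPV map from an investible-flux stack
#'
#' Applies [npv_per_cell()] per uncertainty track and cell. Viability is
#' judged on the central track (`NPV > 0`, strictly); the break-even price
#' layer also uses central fluxes. With `viable_only = TRUE` the NPV layers
#' are masked on non-viable cells (return-on-investment "from financially
#' viable sites").
#'
#' @param investible A [certify()] result.
#' @param area Cell-area [raster_layer()], ha.
#' @param params A [finance_params()].
#' @param cert A [cert_params()].
#' @param viable_only Mask NPV output on non-viable cells.
#' @return Object of class `npv_map`: `npv_total` and `npv_annualized`
#'   (low/central/high lists of $-per-cell layers; annualized = total /
#'   horizon), `viable` (0/1 layer), `break_even` ($/tCO2 layer), and the
#'   per-track NPV matrices used.
#' @export
npv_map <- function(investible, area, params = finance_params(),
                    cert = investible$params, viable_only = FALSE) {
  g <- investible$flux_total$central$grid
  if (!grids_identical(g, area$grid)) stop_grid_mismatch()
  tracks <- c("low", "central", "high")
  npv_total <- npv_ann <- stats::setNames(vector("list", 3), tracks)
  npv_vals <- stats::setNames(vector("list", 3), tracks)
  for (tr in tracks) {
    npv <- npv_per_cell(investible$flux_fast[[tr]]$values,
                        investible$flux_slow[[tr]]$values,
                        area$values, params, cert)
    npv_vals[[tr]] <- npv
  }
  viable_m <- matrix(as.numeric(npv_vals$central > 0), g$n_rows, g$n_cols)
  viable_m[is.na(npv_vals$central)] <- NA_real_
  for (tr in tracks) {
    v <- npv_vals[[tr]]
    if (viable_only) v[!(viable_m %in% 1)] <- NA_real_
    npv_total[[tr]] <- raster_layer(g, v, "$")
    npv_ann[[tr]] <- raster_layer(g, v / params$horizon, "$/yr")
  }
  be <- break_even_price0(investible$flux_fast$central$values,
                          investible$flux_slow$central$values,
                          area$values, params, cert)
  structure(list(npv_total = npv_total, npv_annualized = npv_ann,
                 viable = raster_layer(g, viable_m, "0/1"),
                 break_even = raster_layer(g, be, "$/tCO2"),
                 params = params, cert = cert),
            class = "npv_map")
}

#' @export
print.npv_map <- function(x, ...) {
  v <- x$viable$values
  cat(sprintf("<npv_map> %.1f%% of assessed cells viable; central NPV of viable cells %.6g $\n",
              100 * mean(v, na.rm = TRUE),
              sum(x$npv_total$central$values[v %in% 1], na.rm = TRUE)))
  invisible(x)
}

#' Price-sensitivity sweep
#'
#' Re-runs the viability analysis over a grid of starting carbon prices
#' (all other assumptions unchanged, including the flat period and the
#' appreciation schedule) and reports the fraction of total investible
#' carbon and of investible area that is financially viable at each price,
#' with low/high bands. Investible cells are eligible cells with positive
#' total flux on the central track.
#'
#' @param investible A [certify()] result.
#' @param area Cell-area [raster_layer()], ha.
#' @param params,cert Parameter objects.
#' @param price_grid Sorted positive starting prices, $/tCO2.
#' @return `data.frame(price0, carbon_frac_low/central/high,
#'   area_frac_low/central/high)`, fractions in \[0, 1\].
#' @export
price_sweep <- function(investible, area, params = finance_params(),
                        cert = investible$params,
                        price_grid = c(1, 5, 10, 15, 25, 50, 100)) {
  if (length(price_grid) == 0) stop("empty price grid", call. = FALSE)
  stopifnot(all(price_grid > 0), !is.unsorted(price_grid))
  inv_cells <- investible$flux_total$central$values > 0 &
    investible$mask$values %in% 1
  inv_cells[is.na(inv_cells)] <- FALSE
  area_v <- area$values
  tracks <- c("low", "central", "high")
  out <- data.frame(price0 = price_grid)
  frac_c <- frac_a <- matrix(NA_real_, length(price_grid), 3,
                             dimnames = list(NULL, tracks))
  for (tr in tracks) {
    flux_v <- investible$flux_total[[tr]]$values
    tot_carbon <- sum(flux_v[inv_cells])
    tot_area <- sum(area_v[inv_cells])
    for (k in seq_along(price_grid)) {
      p <- params; p$price0 <- price_grid[k]
      npv <- npv_per_cell(investible$flux_fast[[tr]]$values,
                          investible$flux_slow[[tr]]$values, area_v, p, cert)
      viable <- inv_cells & npv > 0
      frac_c[k, tr] <- if (tot_carbon > 0) sum(flux_v[viable]) / tot_carbon else 0
      frac_a[k, tr] <- if (tot_area > 0) sum(area_v[viable]) / tot_area else 0
    }
  }
  out$carbon_frac_low <- frac_c[, "low"]
  out$carbon_frac_central <- frac_c[, "central"]
  out$carbon_frac_high <- frac_c[, "high"]
  out$area_frac_low <- frac_a[, "low"]
  out$area_frac_central <- frac_a[, "central"]
  out$area_frac_high <- frac_a[, "high"]
  out
}

#' Cumulative discounted profit curves
#'
#' Aggregates the discounted net cash flow of viable cells year by year.
#' Row `year = 0` carries the (undiscounted) establishment outlay, so the
#' year-by-year differences equal each year's discounted net cash flow and
#' the final row equals the aggregate NPV of viable cells. Viability is
#' per-track (each track is priced as its own self-consistent world). With
#' `zones` supplied, one curve per zone is returned (cells assigned by the
#' cell-center rule) plus the global curve.
#'
#' @param investible A [certify()] result.
#' @param area Cell-area [raster_layer()], ha.
#' @param params,cert Parameter objects.
#' @param zones Optional [zone_set()].
#' @return `data.frame(zone_id, year, cum_low, cum_central, cum_high)`;
#'   `zone_id == "global"` for the all-cell curve.
#' @export
accumulation_curve <- function(investible, area, params = finance_params(),
                               cert = investible$params, zones = NULL) {
  g <- investible$flux_total$central$grid
  groups <- list(global = rep(TRUE, g$n_rows * g$n_cols))
  if (!is.null(zones)) {
    lon <- cell_center_lons(g); lat <- cell_center_lats(g)
    px <- rep(lon, each = g$n_rows); py <- rep(lat, times = g$n_cols)
    taken <- rep(FALSE, length(px))
    for (z in zones) {
      inz <- points_in_rings(px, py, z$rings) & !taken
      taken <- taken | inz
      groups[[z$zone_id]] <- inz
    }
  }
  tracks <- c("low", "central", "high")
  horizon <- params$horizon
  cm <- params$cost_multiplier
  res <- NULL
  for (zid in names(groups)) {
    sel <- groups[[zid]]
    cum <- matrix(0, horizon + 1L, 3, dimnames = list(NULL, tracks))
    for (tr in tracks) {
      ff <- as.vector(investible$flux_fast[[tr]]$values)[sel]
      fs <- as.vector(investible$flux_slow[[tr]]$values)[sel]
      av <- as.vector(area$values)[sel]
      ok <- !is.na(ff) & !is.na(fs) & !is.na(av)
      ff <- ff[ok]; fs <- fs[ok]; av <- av[ok]
      npv <- npv_per_cell(ff, fs, av, params, cert)
      viable <- npv > 0
      ff <- ff[viable]; fs <- fs[viable]; av <- av[viable]
      acc <- -params$establishment_cost * cm * sum(av)
      cum[1L, tr] <- acc
      for (t in seq_len(horizon)) {
        cash <- sum(price_at_year(t, params) * (ff + fs * bgc_ramp(t, cert))) -
          params$maintenance_cost * cm * sum(av)
        acc <- acc + cash / (1 + params$discount)^t
        cum[t + 1L, tr] <- acc
      }
    }
    res <- rbind(res, data.frame(zone_id = zid, year = 0:horizon,
                                 cum_low = cum[, "low"],
                                 cum_central = cum[, "central"],
                                 cum_high = cum[, "high"]))
  }
  res
}
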