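#' Leakage: scale certified flux down
#'
#' Protection can displace deforestation beyond project borders; a leakage
#' fraction `L` removes `L` of every flux component.
#'
#' @param investible A [certify()] result.
#' @param L Leakage fraction in \[0, 1).
#' @export
apply_leakage <- function(investible, L) {
  if (L < 0 || L >= 1) stop("leakage fraction must lie in [0, 1)", call. = FALSE)
  out <- investible
  for (fld in c("flux_fast", "flux_slow", "flux_total",
                "density_fast", "density_slow"))
    for (tr in names(out[[fld]]))
      out[[fld]][[tr]] <- raster_layer(out[[fld]][[tr]]$grid,
                                       out[[fld]][[tr]]$values * (1 - L),
                                       out[[fld]][[tr]]$units)
  out
}

#' Raise the non-permanence buffer
#'
#' Returns certification parameters with the buffer increased by `delta`
#' over the 20% baseline; downstream certification must be re-run.
#'
#' @param cert A [cert_params()].
#' @param delta Additional buffer fraction.
#' @export
apply_extra_buffer <- function(cert = cert_params(), delta) {
  newb <- cert$buffer_fraction + delta
  if (delta < 0 || newb >= 1) stop("buffer out of range", call. = FALSE)
  cert$buffer_fraction <- newb
  cert
}

#' Opportunity-cost exclusion
#'
#' Keeps a cell iff the carbon NPV (central track) strictly exceeds the NPV
#' of the competing land rent, capitalized as a constant-rent annuity over
#' the same horizon and discount rate. Ties are excluded.
#'
#' @param npv An [npv_map()] result.
#' @param rent [raster_layer()] of land rent, $/ha/yr (>= 0).
#' @param area Cell-area [raster_layer()], ha.
#' @param params A [finance_params()].
#' @return 0/1 keep-mask [raster_layer()].
#' @export
opportunity_cost_filter <- function(npv, rent, area,
                                    params = finance_params()) {
  g <- npv$npv_total$central$grid
  if (!grids_identical(g, rent$grid) || !grids_identical(g, area$grid))
    stop_grid_mismatch()
  if (any(rent$values < 0, na.rm = TRUE))
    stop("rent must be non-negative", call. = FALSE)
  npv_rent <- rent$values * area$values *
    annuity_factor(params$horizon, params$discount)
  keep <- npv$npv_total$central$values > npv_rent
  m <- matrix(as.numeric(keep), g$n_rows, g$n_cols)
  raster_layer(g, m, "0/1")
}

profitable_carbon <- function(investible, npv_vals, keep = NULL) {
  tracks <- c("low", "central", "high")
  out <- stats::setNames(numeric(3), tracks)
  for (tr in tracks) {
    viable <- npv_vals[[tr]] > 0
    if (!is.null(keep)) viable <- viable & keep
    viable[is.na(viable)] <- FALSE
    out[tr] <- sum(investible$flux_total[[tr]]$values[viable], na.rm = TRUE)
  }
  out
}

#' Scenario configuration
#'
#' @param label Scenario name for the report.
#' @param leakage_fraction Leakage in \[0, 1).
#' @param cost_multiplier Establishment/maintenance cost scaling (>= 1
#'   inflates, 1 = baseline).
#' @param extra_buffer Additional buffer over the 20% baseline.
#' @param opportunity_filter Apply the land-rent exclusion.
#' @export
scenario_config <- function(label, leakage_fraction = 0, cost_multiplier = 1,
                            extra_buffer = 0, opportunity_filter = FALSE) {
  stopifnot(leakage_fraction >= 0, leakage_fraction < 1,
            cost_multiplier >= 0, extra_buffer >= 0,
            leakage_fraction + 0.2 + extra_buffer < 1)
  list(label = label, leakage_fraction = leakage_fraction,
       cost_multiplier = cost_multiplier, extra_buffer = extra_buffer,
       opportunity_filter = opportunity_filter)
}

#' Run scenario analyses against a baseline
#'
#' For each configuration the certified flux and viability are recomputed
#' from scratch (leakage scaling, buffer re-certification, cost inflation,
#' optional opportunity-cost exclusion) and the profitable carbon volume
#' (sum of total flux over viable cells, per uncertainty track) is reported
#' together with its percentage of the *baseline* profitable volume.
#'
#' @param pools A [build_pool_stack()] result.
#' @param d_annual,mask,area Layers as for [certify()].
#' @param rent [raster_layer()] of land rent, $/ha/yr (needed only when a
#'   config sets `opportunity_filter`).
#' @param configs List of [scenario_config()]s; the baseline row is always
#'   reported first.
#' @param params A [finance_params()] (baseline costs).
#' @param cert A [cert_params()] (baseline buffer).
#' @return `data.frame` with scenario label, profitable carbon
#'   (low/central/high, tCO2/yr), percent of baseline (low/central/high)
#'   and viable area (central, ha).
#' @export
run_scenarios <- function(pools, d_annual, mask, area, rent = NULL,
                          configs = list(), params = finance_params(),
                          cert = cert_params()) {
  eval_one <- function(cfg) {
    cert_s <- cert
    cert_s$buffer_fraction <- cert$buffer_fraction + cfg$extra_buffer
    if (cert_s$buffer_fraction >= 1) stop("buffer out of range", call. = FALSE)
    inv <- certify(pools, d_annual, mask, area, cert_s)
    if (cfg$leakage_fraction > 0) inv <- apply_leakage(inv, cfg$leakage_fraction)
    par_s <- params
    par_s$cost_multiplier <- params$cost_multiplier * cfg$cost_multiplier
    npv_vals <- lapply(stats::setNames(nm = c("low", "central", "high")),
                       function(tr) npv_per_cell(inv$flux_fast[[tr]]$values,
                                                 inv$flux_slow[[tr]]$values,
                                                 area$values, par_s, cert_s))
    keep <- NULL
    if (isTRUE(cfg$opportunity_filter)) {
      if (is.null(rent)) stop("opportunity filter requires a rent layer", call. = FALSE)
      npv_rent <- rent$values * area$values *
        annuity_factor(par_s$horizon, par_s$discount)
      keep <- npv_vals$central > npv_rent
    }
    pc <- profitable_carbon(inv, npv_vals, keep)
    viable_c <- npv_vals$central > 0
    if (!is.null(keep)) viable_c <- viable_c & keep
    viable_c[is.na(viable_c)] <- FALSE
    list(pc = pc, area = sum(area$values[viable_c], na.rm = TRUE))
  }
  base <- eval_one(scenario_config("baseline"))
  rows <- list(data.frame(scenario = "baseline",
                          profitable_tco2_yr_low = base$pc["low"],
                          profitable_tco2_yr_central = base$pc["central"],
                          profitable_tco2_yr_high = base$pc["high"],
                          pct_of_baseline_low = 100,
                          pct_of_baseline_central = 100,
                          pct_of_baseline_high = 100,
                          viable_area_ha = base$area))
  for (cfg in configs) {
    r <- eval_one(cfg)
    pct <- ifelse(base$pc > 0, 100 * r$pc / base$pc, NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = cfg$label,
      profitable_tco2_yr_low = r$pc["low"],
      profitable_tco2_yr_central = r$pc["central"],
      profitable_tco2_yr_high = r$pc["high"],
      pct_of_baseline_low = pct["low"],
      pct_of_baseline_central = pct["central"],
      pct_of_baseline_high = pct["high"],
      viable_area_ha = r$area)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
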