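#' Zone assignment by the cell-center rule
#'
#' Assigns every cell to the first zone (in file order) whose polygon
#' contains its center, or 0 if none does.
#'
#' @param grid A [grid_spec()].
#' @param zones A [zone_set()].
#' @return Integer vector over cells in column-major order.
#' @export
zone_assignment <- function(grid, zones) {
  lon <- cell_center_lons(grid); lat <- cell_center_lats(grid)
  px <- rep(lon, each = grid$n_rows); py <- rep(lat, times = grid$n_cols)
  zid <- integer(length(px))
  for (i in seq_along(zones)) {
    z <- zones[[i]]
    bb <- ring_bbox(z$rings)
    cand <- which(zid == 0L & px >= bb["xmin"] & px <= bb["xmax"] &
                    py >= bb["ymin"] & py <= bb["ymax"])
    if (length(cand))
      zid[cand[points_in_rings(px[cand], py[cand], z$rings)]] <- i
  }
  zid
}

round_1000 <- function(x) round(x / 1000) * 1000

#' Country / region / global summary table
#'
#' Per-zone sums of investible flux (all eligible cells, tCO2/yr) and of
#' annualized NPV over financially viable cells ($/yr), with an uncertainty
#' column equal to the half-range of the low/high tracks, rolled up to
#' regions and the global total. Roll-ups are exact sums of the country
#' values (conservation holds to machine precision pre-rounding); rounding
#' to the nearest 1000 is applied at emission time only, via `rounded`.
#'
#' @param investible A [certify()] result.
#' @param npv An [npv_map()] result (computed with `viable_only = FALSE`).
#' @param zones A [zone_set()] partitioning the grid.
#' @param rounded Round outputs to the nearest 1000.
#' @return `data.frame(level, region, country, investible_tco2_yr,
#'   investible_unc, npv_usd_yr, npv_unc)` with country rows first, then
#'   region and global roll-ups.
#' @export
summarize_zones <- function(investible, npv, zones, rounded = FALSE) {
  g <- investible$flux_total$central$grid
  zid <- zone_assignment(g, zones)
  viable <- as.vector(npv$viable$values) %in% 1
  sum_by <- function(vals, sel) {
    out <- numeric(length(zones))
    s <- stats::aggregate(vals[sel], list(zone = zid[sel]), sum)
    s <- s[s$zone > 0, , drop = FALSE]
    out[s$zone] <- s$x
    out
  }
  flux <- lapply(investible$flux_total, function(l) {
    v <- as.vector(l$values); v[is.na(v)] <- 0; v
  })
  npvv <- lapply(npv$npv_annualized, function(l) {
    v <- as.vector(l$values); v[is.na(v)] <- 0; v
  })
  all_cells <- rep(TRUE, length(zid))
  country <- data.frame(
    level = "country",
    region = vapply(zones, function(z) z$region_id, ""),
    country = vapply(zones, function(z) z$zone_id, ""),
    investible_tco2_yr = sum_by(flux$central, all_cells),
    investible_low = sum_by(flux$low, all_cells),
    investible_high = sum_by(flux$high, all_cells),
    npv_usd_yr = sum_by(npvv$central, viable),
    npv_low = sum_by(npvv$low, viable),
    npv_high = sum_by(npvv$high, viable))
  roll <- function(df, level, region, country_lab) {
    data.frame(level = level, region = region, country = country_lab,
               investible_tco2_yr = sum(df$investible_tco2_yr),
               investible_low = sum(df$investible_low),
               investible_high = sum(df$investible_high),
               npv_usd_yr = sum(df$npv_usd_yr),
               npv_low = sum(df$npv_low),
               npv_high = sum(df$npv_high))
  }
  regions <- do.call(rbind, lapply(split(country, country$region), function(d)
    roll(d, "region", d$region[1], "")))
  globalr <- roll(country, "global", "Global", "")
  out <- rbind(country, regions, globalr)
  out$investible_unc <- (out$investible_high - out$investible_low) / 2
  out$npv_unc <- (out$npv_high - out$npv_low) / 2
  out <- out[, c("level", "region", "country", "investible_tco2_yr",
                 "investible_unc", "npv_usd_yr", "npv_unc",
                 "investible_low", "investible_high", "npv_low", "npv_high")]
  rownames(out) <- NULL
  if (rounded)
    for (cc in c("investible_tco2_yr", "investible_unc", "npv_usd_yr",
                 "npv_unc", "investible_low", "investible_high",
                 "npv_low", "npv_high"))
      out[[cc]] <- round_1000(out[[cc]])
  out
}

#' Run the full carbon-prospecting pipeline on a world
#'
#' Chains every stage: cell areas, annualized deforestation, eligibility,
#' pool stack, certification, NPV mapping, price sweep, accumulation
#' curves, zonal summary, VCU validation, and the standard scenario set
#' (leakage 10/20/30%, costs x1.5/x2.0, extra buffer +10/20/30%,
#' opportunity-cost exclusion).
#'
#' @param world A [generate_world()] / [read_world()] world.
#' @param pool_par,cert_par,fin_par Parameter objects.
#' @param price_grid Starting prices for the sweep, $/tCO2.
#' @param constant_area Use constant nominal cell areas.
#' @return Object of class `prospect_run` with elements `area`, `d_annual`,
#'   `mask`, `pools`, `investible`, `npv`, `sweep`, `curves`, `summary`,
#'   `validation`, `scenarios`, `params`.
#' @export
run_pipeline <- function(world, pool_par = pool_params(),
                         cert_par = cert_params(),
                         fin_par = finance_params(),
                         price_grid = c(1, 5, 10, 15, 25, 50, 100),
                         constant_area = FALSE) {
  g <- world$agb$grid
  area <- cell_area_ha(g, constant = constant_area)
  d_annual <- annualize_deforestation(world$d_total, world$horizon_years)
  mask <- eligibility_mask(world$landcover, world$eligible_codes,
                           world$recent_loss, world$settlements)
  pools <- build_pool_stack(world$agb, world$agb_sd, world$soc, pool_par)
  investible <- certify(pools, d_annual, mask, area, cert_par)
  npv <- npv_map(investible, area, fin_par, cert_par)
  sweep <- price_sweep(investible, area, fin_par, cert_par, price_grid)
  curves <- accumulation_curve(investible, area, fin_par, cert_par,
                               world$zones)
  summary_tab <- summarize_zones(investible, npv, world$zones)
  validation <- if (length(world$projects) >= 3)
    validate_against_vcus(investible, world$projects) else NULL
  configs <- c(
    lapply(c(0.1, 0.2, 0.3), function(L)
      scenario_config(sprintf("leakage_%.0f%%", 100 * L), leakage_fraction = L)),
    lapply(c(1.5, 2.0), function(m)
      scenario_config(sprintf("cost_x%.1f", m), cost_multiplier = m)),
    lapply(c(0.1, 0.2, 0.3), function(b)
      scenario_config(sprintf("buffer_+%.0f%%", 100 * b), extra_buffer = b)),
    list(scenario_config("opportunity_cost", opportunity_filter = TRUE)))
  scen <- run_scenarios(pools, d_annual, mask, area, world$rent, configs,
                        fin_par, cert_par)
  structure(list(area = area, d_annual = d_annual, mask = mask,
                 pools = pools, investible = investible, npv = npv,
                 sweep = sweep, curves = curves, summary = summary_tab,
                 validation = validation, scenarios = scen,
                 zones = world$zones,
                 params = list(pool = pool_par, cert = cert_par,
                               fin = fin_par, price_grid = price_grid)),
            class = "prospect_run")
}

#' @export
print.prospect_run <- function(x, ...) {
  gl <- x$summary[x$summary$level == "global", ]
  cat(sprintf("<prospect_run> investible %.6g +/- %.3g tCO2/yr; NPV %.6g +/- %.3g $/yr; %.1f%% of cells viable\n",
              gl$investible_tco2_yr, gl$investible_unc, gl$npv_usd_yr,
              gl$npv_unc, 100 * mean(x$npv$viable$values, na.rm = TRUE)))
  invisible(x)
}

#' Write pipeline products to a run directory
#'
#' Emits the central/low/high investible-flux and NPV layers plus the
#' viability and break-even maps as ASCII grids, all tables as CSV, and a
#' plain-text log of every effective parameter.
#'
#' @param run A [run_pipeline()] result.
#' @param outdir Output directory.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (tr in c("low", "central", "high")) {
    write_ascii_grid(run$investible$flux_total[[tr]],
                     file.path(outdir, sprintf("flux_total_%s.asc", tr)))
    write_ascii_grid(run$npv$npv_total[[tr]],
                     file.path(outdir, sprintf("npv_total_%s.asc", tr)))
    write_ascii_grid(run$npv$npv_annualized[[tr]],
                     file.path(outdir, sprintf("npv_annualized_%s.asc", tr)))
  }
  write_ascii_grid(run$mask, file.path(outdir, "eligibility_mask.asc"))
  write_ascii_grid(run$npv$viable, file.path(outdir, "viable.asc"))
  be <- run$npv$break_even
  be_out <- raster_layer(be$grid,
                         ifelse(is.infinite(be$values), be$grid$nodata,
                                be$values), be$units)
  be_out$values[is.infinite(be$values)] <- NA_real_
  write_ascii_grid(be_out, file.path(outdir, "break_even_price0.asc"))
  utils::write.csv(run$sweep, file.path(outdir, "price_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(run$curves, file.path(outdir, "accumulation_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary, file.path(outdir, "summary_table.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize_zones(run$investible, run$npv, run$zones,
                                   rounded = TRUE),
                   file.path(outdir, "summary_table_rounded.csv"),
                   row.names = FALSE)
  utils::write.csv(run$scenarios, file.path(outdir, "scenario_report.csv"),
                   row.names = FALSE)
  if (!is.null(run$validation)) {
    utils::write.csv(run$validation$pairs,
                     file.path(outdir, "validation_pairs.csv"),
                     row.names = FALSE)
    s <- run$validation$stats
    utils::write.csv(data.frame(n = s$n, pearson_r = s$pearson_r,
                                rmse = s$rmse, t_stat = s$t_stat,
                                p_value = s$p_value, df = s$df),
                     file.path(outdir, "validation_stats.csv"),
                     row.names = FALSE)
  }
  log_params(run, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

log_params <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dump_list <- function(name, x) {
    writeLines(sprintf("[%s]", name), con)
    for (nm in names(x))
      if (is.atomic(x[[nm]]))
        writeLines(sprintf("%s = %s", nm,
                           paste(format(x[[nm]], digits = 15), collapse = ", ")), con)
  }
  dump_list("pool_params", run$params$pool)
  dump_list("cert_params", run$params$cert)
  dump_list("finance_params", run$params$fin)
  writeLines(sprintf("price_grid = %s",
                     paste(run$params$price_grid, collapse = ", ")), con)
}
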