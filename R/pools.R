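#' Carbon-pool conversion parameters
#'
#' Defaults follow standard avoided-deforestation carbon accounting: a
#' biomass-to-carbon stoichiometric factor of 0.475 (central) bracketed by
#' 0.45 and 0.50, a C-to-CO2 mass conversion of 3.67, and two global
#' root-to-shoot allometric models for belowground biomass,
#' `0.489 * agb^0.89` and `0.26 * agb` (t/ha).
#'
#' @param stoich_central,stoich_low,stoich_high Biomass carbon fractions.
#' @param co2_factor C -> CO2 mass ratio (44/12, conventionally 3.67).
#' @param allom1_coef,allom1_exp Power-law root-to-shoot model coefficients.
#' @param allom2_coef Linear root-to-shoot coefficient.
#' @export
pool_params <- function(stoich_central = 0.475, stoich_low = 0.45,
                        stoich_high = 0.50, co2_factor = 3.67,
                        allom1_coef = 0.489, allom1_exp = 0.89,
                        allom2_coef = 0.26) {
  stopifnot(0 < stoich_low, stoich_low <= stoich_central,
            stoich_central <= stoich_high, stoich_high < 1, co2_factor > 1)
  structure(list(stoich_central = stoich_central, stoich_low = stoich_low,
                 stoich_high = stoich_high, co2_factor = co2_factor,
                 allom1_coef = allom1_coef, allom1_exp = allom1_exp,
                 allom2_coef = allom2_coef),
            class = "pool_params")
}

#' Aboveground biomass to CO2 density
#'
#' `agb * s * co2_factor`: dry biomass (t/ha) times the stoichiometric carbon
#' fraction times the C-to-CO2 conversion, giving tCO2/ha.
#'
#' @param agb Aboveground biomass, t/ha (vector/matrix, >= 0).
#' @param s Stoichiometric factor.
#' @param co2_factor C -> CO2 ratio.
#' @export
agb_to_agc_co2 <- function(agb, s = 0.475, co2_factor = 3.67) {
  if (any(agb < 0, na.rm = TRUE)) stop("negative biomass", call. = FALSE)
  agb * s * co2_factor
}

#' Belowground biomass from aboveground biomass
#'
#' Evaluates both allometric models and their cell-wise mean/min/max
#' envelope (all t/ha).
#'
#' @param agb Aboveground biomass, t/ha (>= 0).
#' @param params A [pool_params()].
#' @return List with `eq1`, `eq2`, `mean`, `min`, `max`.
#' @export
bgb_from_agb <- function(agb, params = pool_params()) {
  if (any(agb < 0, na.rm = TRUE)) stop("negative biomass", call. = FALSE)
  eq1 <- params$allom1_coef * agb^params$allom1_exp
  eq2 <- params$allom2_coef * agb
  list(eq1 = eq1, eq2 = eq2,
       mean = (eq1 + eq2) / 2, min = pmin(eq1, eq2), max = pmax(eq1, eq2))
}

#' Topsoil organic carbon to CO2 density
#'
#' @param soc Topsoil (0-30 cm) organic carbon density, tC/ha (>= 0).
#' @param co2_factor C -> CO2 ratio.
#' @export
soc_to_co2 <- function(soc, co2_factor = 3.67) {
  if (any(soc < 0, na.rm = TRUE)) stop("negative soil carbon", call. = FALSE)
  soc * co2_factor
}

#' Build the three-pool CO2 stack with a low/central/high ensemble
#'
#' Converts biomass and soil inputs to per-cell CO2 density (tCO2/ha) for
#' the aboveground (AGC), belowground (BGC) and soil (SOC) pools. Each pool
#' carries a deterministic low/central/high track combining the three
#' uncertainty sources in a worst/central/best composition:
#' \itemize{
#'   \item central: stoichiometry 0.475, mean of the two allometric
#'     predictions, biomass as reported;
#'   \item low: stoichiometry 0.45, cell-wise minimum prediction, biomass
#'     reduced by one standard deviation (clipped at 0);
#'   \item high: stoichiometry 0.50, cell-wise maximum prediction, biomass
#'     increased by one standard deviation.
#' }
#' The soil pool has no uncertainty model; its three tracks coincide.
#'
#' @param agb,agb_sd,soc [raster_layer()]s on one grid: biomass (t/ha), its
#'   standard deviation (t/ha, >= 0), topsoil carbon (tC/ha).
#' @param params A [pool_params()].
#' @return Object of class `carbon_pool_stack`: `agc`, `bgc`, `soc`, each a
#'   list of low/central/high [raster_layer()]s in tCO2/ha.
#' @export
build_pool_stack <- function(agb, agb_sd, soc, params = pool_params()) {
  if (!grids_identical(agb$grid, agb_sd$grid) ||
      !grids_identical(agb$grid, soc$grid)) stop_grid_mismatch()
  if (any(agb_sd$values < 0, na.rm = TRUE))
    stop("agb_sd must be non-negative", call. = FALSE)
  g <- agb$grid
  f <- params$co2_factor
  track <- function(agb_v, s, bgb_pick) {
    bgb <- bgb_from_agb(agb_v, params)[[bgb_pick]]
    list(agc = agb_to_agc_co2(agb_v, s, f), bgc = bgb * s * f)
  }
  lo <- track(pmax(agb$values - agb_sd$values, 0), params$stoich_low, "min")
  ce <- track(agb$values, params$stoich_central, "mean")
  hi <- track(agb$values + agb_sd$values, params$stoich_high, "max")
  lyr <- function(v) raster_layer(g, v, "tCO2/ha")
  soc_co2 <- lyr(soc_to_co2(soc$values, f))
  structure(list(
    agc = list(low = lyr(lo$agc), central = lyr(ce$agc), high = lyr(hi$agc)),
    bgc = list(low = lyr(lo$bgc), central = lyr(ce$bgc), high = lyr(hi$bgc)),
    soc = list(low = soc_co2, central = soc_co2, high = soc_co2),
    params = params), class = "carbon_pool_stack")
}

#' @export
print.carbon_pool_stack <- function(x, ...) {
  cat("<carbon_pool_stack> pools agc/bgc/soc with low/central/high tracks [tCO2/ha]\n")
  invisible(x)
}
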