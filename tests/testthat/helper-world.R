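# Shared fixtures, generated in code and cached per test run.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .world_cache))
    assign(key, force(expr), envir = .world_cache)
  get(key, envir = .world_cache)
}

small_world <- function() cached("small", generate_world(
  synth_config(n_rows = 50, n_cols = 50, seed = 1001L, n_truth_cells = 300,
               n_projects = 6)))

big_world <- function() cached("big", generate_world(
  synth_config(n_rows = 200, n_cols = 200, seed = 2002L,
               n_truth_cells = 1000)))

small_run <- function() cached("small_run", run_pipeline(small_world()))
big_run <- function() cached("big_run", run_pipeline(big_world()))

# a pool stack with all three tracks identical, for hand-arithmetic checks
uniform_stack <- function(grid, agc, bgc, soc) {
  lyr <- function(v) raster_layer(grid, v, "tCO2/ha")
  structure(list(
    agc = list(low = lyr(agc), central = lyr(agc), high = lyr(agc)),
    bgc = list(low = lyr(bgc), central = lyr(bgc), high = lyr(bgc)),
    soc = list(low = lyr(soc), central = lyr(soc), high = lyr(soc)),
    params = pool_params()), class = "carbon_pool_stack")
}

# independent closed-form NPV for a pure fast flux (geometric series):
# flat-price annuity + growing annuity after the flat period
closed_form_npv_fast <- function(ff, area, p) {
  v <- 1 / (1 + p$discount)
  g <- 1 + p$appreciation
  n_flat <- p$flat_years
  n_grow <- p$horizon - p$flat_years
  pv_flat <- v * (1 - v^n_flat) / (1 - v)
  gv <- g * v
  pv_grow <- v^n_flat * gv * (1 - gv^n_grow) / (1 - gv)
  pv_ann <- v * (1 - v^p$horizon) / (1 - v)
  cm <- p$cost_multiplier
  -p$establishment_cost * cm * area +
    p$price0 * ff * (pv_flat + pv_grow) -
    p$maintenance_cost * cm * area * pv_ann
}
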