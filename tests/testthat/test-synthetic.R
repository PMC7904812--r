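test_that("identical seeds reproduce identical worlds bit for bit", {
  cfg <- synth_config(n_rows = 30, n_cols = 30, seed = 77L,
                      n_truth_cells = 40, n_projects = 3)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  for (nm in c("agb", "agb_sd", "soc", "landcover", "d_total",
               "recent_loss", "settlements", "rent"))
    expect_identical(w1[[nm]]$values, w2[[nm]]$values)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$projects[[2]]$vcu_series, w2$projects[[2]]$vcu_series)
  w3 <- generate_world(synth_config(n_rows = 30, n_cols = 30, seed = 78L,
                                    n_truth_cells = 40, n_projects = 3))
  expect_false(identical(w1$agb$values, w3$agb$values))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(generate_world(synth_config(n_rows = 10, n_cols = 10,
                                        n_truth_cells = 5, n_projects = 0)))
  expect_identical(rnorm(1), a)
})

test_that("planted fractions are honoured exactly", {
  cfg <- synth_config(n_rows = 40, n_cols = 40, seed = 9L,
                      frac_ineligible_lc = 0.25, frac_recent_loss = 0.05,
                      frac_settlement = 0.02, n_truth_cells = 5)
  w <- generate_world(cfg)
  n <- 1600
  expect_equal(sum(w$landcover$values != 1), round(0.25 * n))
  expect_equal(sum(w$recent_loss$values), round(0.05 * n))
  expect_equal(sum(w$settlements$values), round(0.02 * n))

  # forcing every exclusion off gives an all-eligible tropics
  w0 <- generate_world(synth_config(n_rows = 20, n_cols = 20, seed = 9L,
                                    frac_ineligible_lc = 0,
                                    frac_recent_loss = 0,
                                    frac_settlement = 0, n_truth_cells = 5))
  expect_true(all(w0$eligible$values == 1))
})

test_that("generated fields match their target moments", {
  w <- generate_world(synth_config(n_rows = 200, n_cols = 200, seed = 14L,
                                   n_truth_cells = 5, n_projects = 0))
  agb <- w$agb$values
  expect_equal(mean(agb), 150, tolerance = 0.05)
  expect_equal(sd(agb) / mean(agb), 0.5, tolerance = 0.15)
  expect_true(all(agb > 0))
  expect_true(all(w$soc$values >= 0))
  expect_true(all(w$d_total$values >= 0 & w$d_total$values <= 1))
  # beta-mean oracle: smoothing preserves the mean loss fraction
  expect_equal(mean(w$d_total$values), 1 / (1 + 9), tolerance = 0.03)
  # spatial autocorrelation: neighbours correlate far more than distant cells
  v <- agb
  lag1 <- cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  far <- cor(as.vector(v[, 1:50]), as.vector(v[, 151:200]))
  expect_gt(lag1, 0.8)
  expect_lt(abs(far), 0.5)
})

test_that("countries partition the grid and regions cover all countries", {
  w <- small_world()
  g <- w$agb$grid
  zid <- zone_assignment(g, w$zones)
  expect_true(all(zid > 0))  # every cell in exactly one country
  s <- zonal_sum(w$agb, w$zones)
  expect_identical(sum(s$sum), sum(w$agb$values))
  expect_true(length(unique(s$region_id)) >= 2)
})

test_that("the scalar truth oracle matches the pipeline exactly", {
  w <- small_world()
  r <- small_run()
  tr <- w$truth
  for (track in c("low", "central", "high")) {
    pipe <- as.vector(r$investible$flux_total[[track]]$values)[tr$cell]
    expect_identical(pipe, tr[[paste0("flux_", track)]])
    npv_pipe <- as.vector(r$npv$npv_total[[track]]$values)[tr$cell]
    truthv <- tr[[paste0("npv_", track)]]
    expect_lt(max(abs(npv_pipe - truthv) / pmax(abs(truthv), 1e-6)), 1e-9)
  }
})

test_that("oracle limiting cases behave", {
  # zero biomass and soil: no flux, NPV is minus the PV of costs
  o <- truth_oracle(0, 0, 0, 0.5, 1, 10)
  expect_equal(o$central$flux_total, 0)
  expect_equal(o$central$npv, -10 * (25 + 10 * (1 - 1.1^-30) / 0.1),
               tolerance = 1e-9)
  # full buffer: zero investible flux, costs still accrue
  o2 <- truth_oracle(200, 0, 50, 0.3, 1, 10,
                     cert = structure(list(buffer_fraction = 1,
                                           bgc_decay_years = 10L),
                                      class = "cert_params"))
  expect_equal(o2$central$flux_total, 0)
})

test_that("noise-free worlds recover perfect validation statistics", {
  w <- generate_world(synth_config(n_rows = 40, n_cols = 40, seed = 15L,
                                   vcu_noise_cv = 0, n_projects = 8,
                                   n_truth_cells = 5))
  inv <- certify(build_pool_stack(w$agb, w$agb_sd, w$soc),
                 annualize_deforestation(w$d_total, w$horizon_years),
                 w$eligible, cell_area_ha(w$agb$grid))
  st <- validate_against_vcus(inv, w$projects)$stats
  expect_equal(st$pearson_r, 1, tolerance = 1e-9)
  expect_equal(st$rmse, 0, tolerance = 1e-9)
  expect_equal(st$t_stat, 0, tolerance = 1e-6)
})
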