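test_that("the carbon-price schedule is flat then appreciating", {
  p <- finance_params()
  expect_equal(price_at_year(3, p), 5.8)
  expect_equal(price_at_year(5, p), 5.8)
  expect_equal(price_at_year(6, p), 5.8 * 1.05)
  expect_equal(price_at_year(30, p), 5.8 * 1.05^25)
  expect_equal(price_at_year(30, p), 19.64, tolerance = 1e-3)
  expect_error(price_at_year(0, p), "out of range")
  expect_error(price_at_year(31, p), "out of range")
})

test_that("zero-flux NPV equals minus the annuity present value of costs", {
  p <- finance_params()
  a30 <- (1 - 1.1^-30) / 0.1
  expect_equal(npv_per_cell(0, 0, 1, p), -(25 + 10 * a30), tolerance = 1e-12)
  expect_equal(-(25 + 10 * a30), -119.27, tolerance = 1e-4)
})

test_that("the year-loop engine matches the closed-form geometric series", {
  set.seed(20)
  for (i in 1:200) {
    p <- finance_params(
      establishment_cost = runif(1, 0, 100),
      maintenance_cost = runif(1, 0, 50),
      price0 = runif(1, 0.5, 60),
      flat_years = sample(0:10, 1),
      appreciation = runif(1, 0, 0.12),
      horizon = sample(10:40, 1),
      discount = runif(1, 0.02, 0.3),
      cost_multiplier = runif(1, 0.5, 2))
    ff <- runif(1, 0, 500); area <- runif(1, 1, 200)
    got <- npv_per_cell(ff, 0, area, p)
    want <- closed_form_npv_fast(ff, area, p)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("NPV is affine in price and flux, with revenue linearity", {
  p <- finance_params()
  ct <- cert_params()
  base <- npv_per_cell(10, 4, 50, p, ct)
  dbl <- npv_per_cell(20, 8, 50, p, ct)
  pvcost <- -npv_per_cell(0, 0, 50, p, ct)
  expect_equal(dbl + pvcost, 2 * (base + pvcost), tolerance = 1e-9)

  p2 <- p; p2$price0 <- 2 * p$price0
  expect_equal(npv_per_cell(10, 4, 50, p2, ct) + pvcost,
               2 * (base + pvcost), tolerance = 1e-9)
  expect_gt(npv_per_cell(10, 4, 50, p2, ct), base)
})

test_that("break-even price is the exact NPV root and matches bisection", {
  p <- finance_params(); ct <- cert_params()
  set.seed(21)
  for (i in 1:25) {
    ff <- runif(1, 0.1, 30); fs <- runif(1, 0, 10); area <- runif(1, 1, 100)
    be <- break_even_price0(ff, fs, area, p, ct)
    at_be <- function(pr) {
      pp <- p; pp$price0 <- pr
      npv_per_cell(ff, fs, area, pp, ct)
    }
    expect_equal(at_be(be), 0, tolerance = 1e-6)
    expect_lt(at_be(be * (1 - 1e-6)), 0)
    expect_gt(at_be(be * (1 + 1e-6)), 0)
    # bisection oracle
    lo <- 0; hi <- 1e4
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (at_be(mid) > 0) hi <- mid else lo <- mid
    }
    expect_equal(be, (lo + hi) / 2, tolerance = 1e-6)
  }
  # default-parameter break-even fast flux per hectare ~ 1.61 tCO2/ha/yr
  t <- 1:30
  relp <- ifelse(t <= 5, 1, 1.05^(t - 5))
  pv_unit <- sum(relp * 1.1^-t) * 5.8
  pv_cost <- 25 + 10 * (1 - 1.1^-30) / 0.1
  flux_star <- pv_cost / pv_unit
  expect_equal(flux_star, 1.61, tolerance = 2e-3)
  expect_equal(npv_per_cell(flux_star, 0, 1, p), 0, tolerance = 1e-9)
  expect_equal(break_even_price0(flux_star, 0, 1, p, ct), 5.8,
               tolerance = 1e-9)
  expect_equal(break_even_price0(0, 0, 1, p, ct), Inf)
})

test_that("npv_map agrees with the scalar engine and flags viability", {
  r <- small_run()
  w <- small_world()
  nm <- r$npv
  # per-cell equality with the scalar oracle at the truth sample
  tr <- w$truth
  pipe <- as.vector(nm$npv_total$central$values)[tr$cell]
  rel <- abs(pipe - tr$npv_central) / pmax(abs(tr$npv_central), 1e-6)
  expect_lt(max(rel), 1e-9)
  # viability consistent with the strict NPV > 0 rule
  v <- nm$viable$values
  npv_c <- nm$npv_total$central$values
  expect_identical(v[!is.na(v)] == 1, npv_c[!is.na(v)] > 0)
  expect_equal(nm$npv_annualized$central$values,
               nm$npv_total$central$values / 30)
  # break-even consistency: viable iff break-even <= price0 (positive flux)
  flux <- r$investible$flux_total$central$values
  sel <- !is.na(v) & flux > 0
  expect_identical(v[sel] == 1, nm$break_even$values[sel] < 5.8 |
                     abs(nm$break_even$values[sel] - 5.8) < 1e-12)
})

test_that("degenerate flux worlds give all-or-nothing viability", {
  g <- grid_spec(0, 0.03, 0.01, 3, 3)
  st0 <- uniform_stack(g, 0, 0, 0)
  mask <- raster_layer(g, 1); area <- cell_area_ha(g)
  inv0 <- certify(st0, raster_layer(g, 0.02), mask, area)
  nm0 <- npv_map(inv0, area)
  expect_true(all(nm0$viable$values == 0))
  stbig <- uniform_stack(g, 5000, 1000, 1000)
  invb <- certify(stbig, raster_layer(g, 0.05), mask, area)
  nmb <- npv_map(invb, area)
  expect_true(all(nmb$viable$values == 1))
})

test_that("the price sweep equals the break-even map share and saturates", {
  r <- small_run()
  sweep <- r$sweep
  inv <- r$investible
  flux_v <- inv$flux_total$central$values
  inv_cells <- flux_v > 0 & inv$mask$values %in% 1
  inv_cells[is.na(inv_cells)] <- FALSE
  be <- r$npv$break_even$values
  total <- sum(flux_v[inv_cells])
  for (k in seq_len(nrow(sweep))) {
    p <- sweep$price0[k]
    share <- sum(flux_v[inv_cells & be < p]) / total
    expect_equal(sweep$carbon_frac_central[k], share)
  }
  expect_true(all(diff(sweep$carbon_frac_central) >= 0))
  expect_true(all(diff(sweep$area_frac_central) >= 0))
})

test_that("accumulation curves telescope to the aggregate NPV of viable cells", {
  r <- small_run()
  cur <- r$curves[r$curves$zone_id == "global", ]
  nm <- r$npv
  v <- nm$viable$values %in% 1
  expect_equal(cur$cum_central[cur$year == 30],
               sum(nm$npv_total$central$values[v], na.rm = TRUE),
               tolerance = 1e-6)
  # single-cell world: curve equals the cell's own discounted cash flows
  g <- grid_spec(0, 0.01, 0.01, 1, 1)
  st <- uniform_stack(g, 2000, 400, 300)
  area <- cell_area_ha(g)
  inv1 <- certify(st, raster_layer(g, 0.05), raster_layer(g, 1), area)
  cur1 <- accumulation_curve(inv1, area)
  p <- finance_params(); ct <- cert_params()
  ff <- inv1$flux_fast$central$values[1, 1]
  fs <- inv1$flux_slow$central$values[1, 1]
  a <- area$values[1, 1]
  acc <- -25 * a
  for (t in 1:30) {
    acc <- acc + (price_at_year(t, p) * (ff + fs * min(t, 10) / 10) - 10 * a) / 1.1^t
    expect_equal(cur1$cum_central[cur1$year == t], acc, tolerance = 1e-9)
  }
  expect_equal(acc, npv_per_cell(ff, fs, a, p, ct), tolerance = 1e-9)
})
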