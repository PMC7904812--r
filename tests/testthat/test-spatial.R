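make_grid <- function(nr = 10, nc = 12, cs = 0.1, lon0 = -1, lat0 = 1)
  grid_spec(lon0, lat0, cs, nr, nc)

test_that("bilinear resampling reproduces constants, nodes, and affine ramps", {
  src <- make_grid(20, 20, 0.05)
  tgt <- make_grid(8, 8, 0.1, lon0 = -0.9, lat0 = 0.9)

  const <- raster_layer(src, 7.0)
  expect_equal(resample_bilinear(const, tgt)$values,
               matrix(7.0, 8, 8))

  # target center coinciding with a source center returns it unchanged
  set.seed(1)
  v <- matrix(rnorm(400), 20, 20)
  lay <- raster_layer(src, v)
  tgt1 <- grid_spec(src$origin_lon + 3 * 0.05, src$origin_lat - 4 * 0.05,
                    0.05, 1, 1)
  expect_identical(resample_bilinear(lay, tgt1)$values[1, 1], v[5, 4])

  # affine field: f(lon, lat) = 3 lon - 2 lat + 0.5 is interpolated exactly
  ramp <- function(lon, lat) 3 * lon - 2 * lat + 0.5
  rv <- outer(cell_center_lats(src), cell_center_lons(src),
              function(la, lo) ramp(lo, la))
  res <- resample_bilinear(raster_layer(src, rv), tgt)
  expected <- outer(cell_center_lats(tgt), cell_center_lons(tgt),
                    function(la, lo) ramp(lo, la))
  expect_lt(max(abs(res$values - expected)), 1e-9)
})

test_that("resampling a layer onto its own grid is the identity", {
  g <- make_grid(15, 17, 0.00833, lon0 = -60, lat0 = 0.1)
  set.seed(2)
  v <- matrix(rexp(15 * 17), 15, 17)
  v[4, 5] <- NA
  out <- resample_bilinear(raster_layer(g, v), g)
  expect_identical(out$values, v)
})

test_that("masked source cells and non-overlapping grids are handled", {
  src <- make_grid(10, 10, 0.1)
  v <- matrix(1.0, 10, 10); v[5, 5] <- NA
  lay <- raster_layer(src, v)
  tgt <- make_grid(5, 5, 0.2, lon0 = -0.9, lat0 = 0.9)  # centers off-node
  out <- resample_bilinear(lay, tgt)
  expect_true(any(is.na(out$values)))  # support includes the masked cell
  far <- make_grid(5, 5, 0.2, lon0 = 50, lat0 = 50)
  expect_error(resample_bilinear(lay, far), "grid mismatch")
})

test_that("tropical clipping retains the closed band and masks outside", {
  g <- grid_spec(0, 26, 1, 52, 3)  # centers 25.5 .. -25.5
  lay <- clip_tropics(raster_layer(g, 1.0))
  lat <- cell_center_lats(g)
  expect_true(all(is.na(lay$values[lat > 23.44, ])))
  expect_true(all(lay$values[abs(lat) <= 23.44, ] == 1))
  # a center exactly on the boundary is retained
  g2 <- grid_spec(0, 23.44 + 0.5, 1, 1, 1)
  expect_equal(clip_tropics(raster_layer(g2, 5))$values[1, 1], 5)
  g3 <- grid_spec(0, 25.0 + 0.5, 1, 1, 1)
  expect_true(is.na(clip_tropics(raster_layer(g3, 5))$values[1, 1]))
})

test_that("cell areas follow spherical geometry", {
  # closed-form check for a ~1 km cell on the equator
  g <- grid_spec(0, 0.00833 / 2, 0.00833, 1, 1)
  R <- 6371000
  half <- 0.00833 / 2 * pi / 180
  expected <- R^2 * (0.00833 * pi / 180) * (sin(half) - sin(-half)) / 1e4
  expect_equal(cell_area_ha(g)$values[1, 1], expected)
  expect_equal(expected, 85.86, tolerance = 1e-3)

  # area ratio ~ cos(latitude) within the tropics
  for (phi in c(5, 15, 23.44)) {
    gp <- grid_spec(0, phi + 0.00833 / 2, 0.00833, 1, 1)
    ratio <- cell_area_ha(gp)$values[1, 1] / expected
    expect_equal(ratio, cos(phi * pi / 180), tolerance = 1e-4)
  }

  # doubling the cell size quadruples the area
  g2 <- grid_spec(0, 0.00833, 0.01666, 1, 1)
  expect_equal(cell_area_ha(g2)$values[1, 1] / expected, 4, tolerance = 1e-6)

  # strictly decreasing with |latitude|, constant within rows
  gg <- grid_spec(0, 30, 0.5, 40, 4)  # all-northern rows: distinct |lat|
  a <- cell_area_ha(gg)$values
  expect_true(all(a == a[, 1]))
  lat <- abs(cell_center_lats(gg))
  expect_true(all(diff(a[order(lat), 1]) < 0))

  # full 360-degree band sums to the spherical band area
  band <- grid_spec(-180, 10, 0.5, 40, 720)
  total <- sum(cell_area_ha(band)$values)
  R2 <- 6371000^2
  exact <- 2 * pi * R2 * (sin(10 * pi / 180) - sin(-10 * pi / 180)) / 1e4
  expect_lt(abs(total - exact) / exact, 0.001)
})

test_that("zonal sums follow the cell-center rule and conserve partitions", {
  g <- grid_spec(0, 1, 0.1, 10, 10)
  ones <- raster_layer(g, 1.0)
  # rectangle covering exactly the 10 centers of rows 1-2, cols 1-5
  z1 <- zone("a", "r1", rect_ring(0, 0.8, 0.5, 1.0))
  expect_equal(zonal_sum(ones, zone_set(list(z1)))$sum, 10)

  # partition into left/right halves conserves the global sum exactly
  set.seed(3)
  v <- matrix(runif(100), 10, 10)
  lay <- raster_layer(g, v)
  zs <- zone_set(list(zone("L", "r", rect_ring(0, 0, 0.5, 1)),
                      zone("R", "r", rect_ring(0.5, 0, 1, 1))))
  s <- zonal_sum(lay, zs)
  expect_identical(sum(s$sum), sum(v))

  # shared-border cells go to the first zone in file order
  zo <- zone_set(list(zone("A", "r", rect_ring(0, 0, 0.55, 1)),
                      zone("B", "r", rect_ring(0.45, 0, 1, 1))))
  so <- zonal_sum(ones, zo)
  expect_equal(sum(so$sum), 100)

  # empty zone warns and reports 0
  ze <- zone_set(list(zone("E", "r", rect_ring(5, 5, 6, 6))))
  expect_warning(se <- zonal_sum(ones, ze), "no cell centers")
  expect_equal(se$sum, 0)
  expect_true(se$empty)
})

test_that("zonal sums match a brute-force point-in-polygon oracle", {
  skip_if_not_installed("sp")
  g <- grid_spec(-1, 1, 0.07, 25, 25)
  set.seed(4)
  v <- matrix(rnorm(625), 25, 25)
  lay <- raster_layer(g, v)
  # an irregular pentagon
  ring <- cbind(lon = c(-0.8, 0.3, 0.6, 0.1, -0.6),
                lat = c(-0.5, -0.7, 0.2, 0.8, 0.5))
  zs <- zone_set(list(zone("p", "r", ring)))
  got <- zonal_sum(lay, zs)$sum

  lon <- cell_center_lons(g); lat <- cell_center_lats(g)
  acc <- 0
  for (i in 1:25) for (j in 1:25) {
    if (sp::point.in.polygon(lon[j], lat[i], ring[, 1], ring[, 2]) > 0)
      acc <- acc + v[i, j]
  }
  expect_equal(got, acc)
})

test_that("raster arithmetic requires identical grids and propagates masks", {
  a <- raster_layer(make_grid(), 2)
  b <- raster_layer(make_grid(), 3)
  expect_equal((a + b)$values[1, 1], 5)
  b$values[2, 2] <- NA
  expect_true(is.na((a * b)$values[2, 2]))
  d <- raster_layer(make_grid(lat0 = 2), 3)
  expect_error(a + d, "grid mismatch")
})
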