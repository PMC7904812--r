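#' Synthetic-world configuration
#'
#' Parameters of the seeded generator that emulates the structure of the
#' real input stack: a spatially autocorrelated positive biomass field with
#' per-cell uncertainty, a soil-carbon field correlated with biomass, a
#' bounded deforestation-risk field, categorical land cover with ineligible
#' classes, sparse recent-loss and settlement masks, a land-rent field, a
#' rectangular partition into mock countries, and project polygons whose
#' issued-credit series are noisy transforms of the generator's own ground
#' truth. Defaults are typical humid-tropics magnitudes: 150 t/ha mean
#' aboveground biomass (CV 0.5), 60 tC/ha topsoil carbon, Beta(1, 9)
#' projected 15-year loss (mean 10%), 30% ineligible land cover, $30/ha/yr
#' mean rent.
#'
#' @param n_rows,n_cols Grid size, cells.
#' @param cell_size Cell size, degrees.
#' @param origin_lon Western edge, degrees.
#' @param origin_lat Northern edge, degrees; the default centers the grid
#'   on the equator so it lies inside the tropical band.
#' @param seed Integer seed; identical seeds give identical worlds.
#' @param correlation_length Autocorrelation scale of the random fields,
#'   cells.
#' @param agb_mean,agb_cv Aboveground biomass mean (t/ha) and coefficient
#'   of variation.
#' @param agb_sd_frac Per-cell biomass SD as a fraction of the value.
#' @param soc_mean Topsoil organic carbon mean, tC/ha.
#' @param soc_corr Weight of the biomass-tracking component of soil carbon
#'   in \[0, 1\].
#' @param defor_alpha,defor_beta Beta shapes of the projected total loss
#'   fraction.
#' @param frac_ineligible_lc,frac_recent_loss,frac_settlement Planted
#'   fractions of ineligible land cover, recent loss, settlements.
#' @param n_countries,n_projects Counts of mock countries and projects.
#' @param vcu_noise_cv CV of the multiplicative lognormal noise on issued
#'   credits (0 = noise-free).
#' @param rent_mean,rent_cv Land-rent field, $/ha/yr.
#' @param horizon_years Deforestation projection period, years.
#' @param n_truth_cells Number of cells at which the scalar truth oracle is
#'   evaluated and stored.
#' @export
synth_config <- function(n_rows = 100, n_cols = 100, cell_size = 0.00833,
                         origin_lon = -60,
                         origin_lat = n_rows * cell_size / 2,
                         seed = 42L, correlation_length = 5,
                         agb_mean = 150, agb_cv = 0.5, agb_sd_frac = 0.2,
                         soc_mean = 60, soc_corr = 0.5,
                         defor_alpha = 1, defor_beta = 9,
                         frac_ineligible_lc = 0.3, frac_recent_loss = 0.05,
                         frac_settlement = 0.02,
                         n_countries = 6, n_projects = 8,
                         vcu_noise_cv = 0.3, rent_mean = 30, rent_cv = 1,
                         horizon_years = 15, n_truth_cells = 1000) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0,
            agb_mean > 0, soc_mean > 0, rent_mean > 0,
            frac_ineligible_lc >= 0, frac_ineligible_lc < 1,
            frac_recent_loss >= 0, frac_recent_loss < 1,
            frac_settlement >= 0, frac_settlement < 1,
            soc_corr >= 0, soc_corr <= 1, vcu_noise_cv >= 0,
            n_countries >= 1, n_projects >= 0)
  structure(as.list(environment()), class = "synth_config")
}

# Separable Gaussian moving-average smoother with reflective padding;
# preserves the mean, deterministic.
smooth_field <- function(m, corr_len) {
  h <- max(1L, ceiling(2 * corr_len))
  w <- stats::dnorm(seq(-h, h), sd = max(corr_len / 2, 0.5))
  w <- w / sum(w)
  pad_filter <- function(x) {
    n <- length(x)
    hh <- min(h, n - 1L)
    xp <- c(rev(x[seq_len(hh)]), x, rev(x[seq(n - hh + 1L, n)]))
    wf <- if (hh == h) w else { ww <- stats::dnorm(seq(-hh, hh), sd = max(corr_len / 2, 0.5)); ww / sum(ww) }
    as.numeric(stats::filter(xp, wf, sides = 2))[seq(hh + 1L, hh + n)]
  }
  m <- apply(m, 2, pad_filter)
  t(apply(m, 1, pad_filter))
}

standardize <- function(m) (m - mean(m)) / stats::sd(as.vector(m))

# Lognormal field with target mean and CV built on a standardized smoothed
# Gaussian field (moment-matched: mean/CV exact in expectation).
lognormal_field <- function(z, mean, cv) {
  sigma <- sqrt(log(1 + cv^2))
  mu <- log(mean) - sigma^2 / 2
  exp(mu + sigma * z)
}

# Recursive rectangular partition of the grid into n blocks, split lines on
# cell edges so every cell center is strictly inside exactly one block.
# Returns a list of c(col0, row0, col1, row1) in 0-based cell units.
partition_grid_rects <- function(grid, n, min_cells = 3L) {
  rects <- list(c(0L, 0L, grid$n_cols, grid$n_rows))
  while (length(rects) < n) {
    sizes <- vapply(rects, function(r) (r[3] - r[1]) * (r[4] - r[2]), 0)
    i <- which.max(sizes)
    r <- rects[[i]]
    w <- r[3] - r[1]; hgt <- r[4] - r[2]
    pick <- function(lo, hi) { v <- seq(lo, hi); v[sample.int(length(v), 1L)] }
    if (w >= hgt && w >= 2 * min_cells) {
      s <- pick(r[1] + min_cells, r[3] - min_cells)
      a <- c(r[1], r[2], s, r[4]); b <- c(s, r[2], r[3], r[4])
    } else if (hgt >= 2 * min_cells) {
      s <- pick(r[2] + min_cells, r[4] - min_cells)
      a <- c(r[1], r[2], r[3], s); b <- c(r[1], s, r[3], r[4])
    } else break
    rects[[i]] <- a
    rects[[length(rects) + 1L]] <- b
  }
  rects
}

rect_cells_to_ring <- function(grid, r) {
  lon0 <- grid$origin_lon + r[1] * grid$cell_size
  lon1 <- grid$origin_lon + r[3] * grid$cell_size
  lat0 <- grid$origin_lat - r[4] * grid$cell_size
  lat1 <- grid$origin_lat - r[2] * grid$cell_size
  rect_ring(lon0, lat0, lon1, lat1)
}

#' Scalar truth oracle for one cell
#'
#' Independent single-cell reimplementation of the certification and
#' pricing arithmetic, used to cross-check the raster pipeline and to
#' derive the ground-truth credits behind synthetic project VCU series.
#' Operates on plain scalars; the NPV term is accumulated as an explicit
#' discounted sum over years.
#'
#' @param agb,agb_sd Aboveground biomass and its SD, t/ha.
#' @param soc Topsoil organic carbon, tC/ha.
#' @param d_total Projected loss fraction over the projection period.
#' @param eligible 0/1 eligibility flag.
#' @param area_ha Cell area, ha.
#' @param pools,cert,fin Parameter objects.
#' @param horizon_years Projection period, years.
#' @return List of per-track (`low`, `central`, `high`) scalars:
#'   `flux_fast`, `flux_slow`, `flux_total` (tCO2/yr) and `npv` ($).
#' @export
truth_oracle <- function(agb, agb_sd, soc, d_total, eligible, area_ha,
                         pools = pool_params(), cert = cert_params(),
                         fin = finance_params(), horizon_years = 15) {
  f <- pools$co2_factor
  d <- d_total / horizon_years
  keep <- 1 - cert$buffer_fraction
  socc <- soc * f
  one_track <- function(a, s, pick) {
    eq1 <- pools$allom1_coef * a^pools$allom1_exp
    eq2 <- pools$allom2_coef * a
    bgb <- switch(pick, min = min(eq1, eq2), mean = (eq1 + eq2) / 2,
                  max = max(eq1, eq2))
    agc <- a * s * f
    bgc <- bgb * s * f
    dens_f <- keep * d * (agc + socc)
    dens_s <- keep * d * bgc
    ff <- dens_f * area_ha * eligible
    fs <- dens_s * area_ha * eligible
    t <- seq_len(fin$horizon)
    price <- ifelse(t <= fin$flat_years, fin$price0,
                    fin$price0 * (1 + fin$appreciation)^(t - fin$flat_years))
    ramp <- pmin(t, cert$bgc_decay_years) / cert$bgc_decay_years
    disc <- (1 + fin$discount)^-t
    cm <- fin$cost_multiplier
    npv <- -fin$establishment_cost * cm * area_ha +
      sum((price * (ff + fs * ramp) - fin$maintenance_cost * cm * area_ha) * disc)
    list(flux_fast = ff, flux_slow = fs, flux_total = ff + fs, npv = npv)
  }
  list(low = one_track(max(agb - agb_sd, 0), pools$stoich_low, "min"),
       central = one_track(agb, pools$stoich_central, "mean"),
       high = one_track(agb + agb_sd, pools$stoich_high, "max"))
}

#' Generate a complete synthetic world
#'
#' Builds every input layer the pipeline consumes, plus mock countries,
#' projects with noisy issued-credit series, and a ground-truth table
#' evaluated with the independent scalar [truth_oracle()] at a seeded
#' sample of cells. All randomness flows from `config$seed` through R's
#' Mersenne-Twister generator with fixed normal/sample kinds, so identical
#' configurations reproduce identical worlds bit for bit.
#'
#' @param config A [synth_config()].
#' @return Object of class `synth_world`: layers (`agb`, `agb_sd`, `soc`,
#'   `landcover`, `d_total`, `recent_loss`, `settlements`, `rent`),
#'   `eligible_codes`, `eligible` flag layer, `zones`, `projects`, `truth`
#'   (data frame of sampled-cell oracle values), and `config`.
#' @export
generate_world <- function(config = synth_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  g <- grid_spec(config$origin_lon, config$origin_lat, config$cell_size,
                 config$n_rows, config$n_cols)
  nr <- g$n_rows; nc <- g$n_cols; ncell <- nr * nc
  cl <- config$correlation_length
  noise <- function() matrix(stats::rnorm(ncell), nr, nc)
  zfield <- function() standardize(smooth_field(noise(), cl))

  agb <- lognormal_field(zfield(), config$agb_mean, config$agb_cv)
  agb_sd <- config$agb_sd_frac * agb
  soc_resid <- lognormal_field(zfield(), config$soc_mean, 0.3)
  soc <- pmax(config$soc_corr * agb * (config$soc_mean / config$agb_mean) +
                (1 - config$soc_corr) * soc_resid, 0)
  d_total <- pmin(pmax(smooth_field(
    matrix(stats::rbeta(ncell, config$defor_alpha, config$defor_beta), nr, nc),
    cl), 0), 1)
  rent <- lognormal_field(zfield(), config$rent_mean, config$rent_cv)

  # land cover: code 1 = forest (eligible); the configured ineligible
  # fraction is planted exactly, on the low tail of a smoothed field so
  # ineligible classes are spatially clumped
  lc <- matrix(1, nr, nc)
  n_inel <- round(config$frac_ineligible_lc * ncell)
  if (n_inel > 0) {
    suit <- zfield()
    idx <- order(as.vector(suit))[seq_len(n_inel)]
    lc[idx] <- sample(2:5, n_inel, replace = TRUE)
  }
  sparse_mask <- function(frac) {
    m <- matrix(0, nr, nc)
    k <- round(frac * ncell)
    if (k > 0) m[sample.int(ncell, k)] <- 1
    m
  }
  recent_loss <- sparse_mask(config$frac_recent_loss)
  settlements <- sparse_mask(config$frac_settlement)

  lyr <- function(v, units) raster_layer(g, v, units)
  world <- list(
    agb = lyr(agb, "t/ha"), agb_sd = lyr(agb_sd, "t/ha"),
    soc = lyr(soc, "tC/ha"), landcover = lyr(lc, "class"),
    d_total = lyr(d_total, "fraction"),
    recent_loss = lyr(recent_loss, "0/1"),
    settlements = lyr(settlements, "0/1"),
    rent = lyr(rent, "$/ha/yr"),
    eligible_codes = 1, horizon_years = config$horizon_years)

  # eligibility flag (land cover + masks + tropics band)
  elig_layer <- eligibility_mask(world$landcover, world$eligible_codes,
                                 world$recent_loss, world$settlements)
  world$eligible <- elig_layer

  # countries: rectangular partition; regions by block centroid longitude
  rects <- partition_grid_rects(g, config$n_countries)
  cent_lon <- vapply(rects, function(r) (r[1] + r[3]) / 2, 0)
  n_regions <- min(3L, length(rects))
  region_of <- as.integer(cut(rank(cent_lon, ties.method = "first"),
                              breaks = n_regions, labels = FALSE))
  world$zones <- zone_set(lapply(seq_along(rects), function(i)
    zone(sprintf("country_%02d", i), sprintf("region_%d", region_of[i]),
         rect_cells_to_ring(g, rects[[i]]))))

  # ground truth at a seeded sample of cells, via the scalar oracle
  area <- cell_area_ha(g)
  elig_v <- elig_layer$values
  n_truth <- min(config$n_truth_cells, ncell)
  truth_idx <- sort(sample.int(ncell, n_truth))
  truth <- do.call(rbind, lapply(truth_idx, function(k) {
    o <- truth_oracle(agb[k], agb_sd[k], soc[k], d_total[k],
                      ifelse(is.na(elig_v[k]), 0, elig_v[k]), area$values[k],
                      horizon_years = config$horizon_years)
    data.frame(cell = k,
               flux_low = o$low$flux_total,
               flux_central = o$central$flux_total,
               flux_high = o$high$flux_total,
               flux_fast_central = o$central$flux_fast,
               flux_slow_central = o$central$flux_slow,
               npv_low = o$low$npv, npv_central = o$central$npv,
               npv_high = o$high$npv)
  }))
  world$truth <- truth

  # projects: random rectangles centred on eligible cells; issued credits
  # are the oracle's central flux times multiplicative lognormal noise
  elig_cells <- which(elig_v %in% 1)
  projects <- list()
  if (config$n_projects > 0 && length(elig_cells) > 0) {
    for (p in seq_len(config$n_projects)) {
      k <- elig_cells[sample.int(length(elig_cells), 1L)]
      r0 <- (k - 1L) %% nr; c0 <- (k - 1L) %/% nr
      hw <- sample(2:5, 1L); hh <- sample(2:5, 1L)
      rc <- c(max(0L, c0 - hw), max(0L, r0 - hh),
              min(nc, c0 + hw), min(nr, r0 + hh))
      cells <- as.vector(outer((rc[2] + 1L):rc[4], ((rc[1] + 1L):rc[3] - 1L) * nr, `+`))
      flux_truth <- sum(vapply(cells, function(kk) {
        truth_oracle(agb[kk], agb_sd[kk], soc[kk], d_total[kk],
                     ifelse(is.na(elig_v[kk]), 0, elig_v[kk]),
                     area$values[kk],
                     horizon_years = config$horizon_years)$central$flux_total
      }, 0))
      n_vint <- sample.int(10L, 1L)
      noise_mult <- if (config$vcu_noise_cv > 0) {
        sig <- sqrt(log(1 + config$vcu_noise_cv^2))
        exp(stats::rnorm(n_vint, -sig^2 / 2, sig))
      } else rep(1, n_vint)
      projects[[p]] <- project_record(
        sprintf("project_%02d", p),
        rect_cells_to_ring(g, rc),
        data.frame(vintage_year = 2004L + seq_len(n_vint),
                   vcu_tco2e = flux_truth * noise_mult))
      projects[[p]]$truth_flux <- flux_truth
    }
  }
  world$projects <- projects
  world$config <- config
  structure(world, class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world> %d x %d cells, %d countries, %d projects, seed %d\n",
              x$agb$grid$n_rows, x$agb$grid$n_cols, length(x$zones),
              length(x$projects), x$config$seed))
  invisible(x)
}

#' Write / read a synthetic world as a plain-text bundle
#'
#' Layers go to ESRI ASCII grids, countries and projects to GeoJSON + CSV,
#' ground truth to CSV, and the full configuration (including the seed) to
#' a JSON manifest.
#'
#' @param world A [generate_world()] result.
#' @param dir Bundle directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("agb", "agb_sd", "soc", "landcover", "d_total",
               "recent_loss", "settlements", "rent"))
    write_ascii_grid(world[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_zones_geojson(world$zones, file.path(dir, "countries.geojson"))
  if (length(world$projects))
    write_projects(world$projects, file.path(dir, "projects.geojson"),
                   file.path(dir, "vcu_series.csv"))
  utils::write.csv(world$truth, file.path(dir, "truth_sample.csv"),
                   row.names = FALSE)
  cfg <- world$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_world
#' @export
read_world <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  units <- c(agb = "t/ha", agb_sd = "t/ha", soc = "tC/ha",
             landcover = "class", d_total = "fraction",
             recent_loss = "0/1", settlements = "0/1", rent = "$/ha/yr")
  world <- lapply(names(units), function(nm)
    read_ascii_grid(file.path(dir, paste0(nm, ".asc")), units[[nm]]))
  names(world) <- names(units)
  world$eligible_codes <- 1
  world$horizon_years <- cfg$horizon_years
  world$zones <- read_zones_geojson(file.path(dir, "countries.geojson"))
  pj <- file.path(dir, "projects.geojson")
  world$projects <- if (file.exists(pj))
    read_projects(pj, file.path(dir, "vcu_series.csv")) else list()
  world$truth <- utils::read.csv(file.path(dir, "truth_sample.csv"))
  world$eligible <- eligibility_mask(world$landcover, world$eligible_codes,
                                     world$recent_loss, world$settlements)
  world$config <- do.call(synth_config, cfg[setdiff(names(cfg), "n_regions")])
  structure(world, class = "synth_world")
}
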