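# smooth random field on an nr x nc grid: coarse white noise bilinearly
# upsampled, so spatial correlation length scales with the coarse cell
smooth_field <- function(nr, nc, coarse = 5, sd = 1) {
  cr <- max(2L, as.integer(coarse))
  base <- matrix(stats::rnorm(cr * cr, sd = sd), cr, cr)
  ri <- seq(1, cr, length.out = nr)
  ci <- seq(1, cr, length.out = nc)
  r0 <- pmin(floor(ri), cr - 1); tr <- ri - r0
  c0 <- pmin(floor(ci), cr - 1); tc <- ci - c0
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    lo <- base[r0, c0[j]] * (1 - tr) + base[r0 + 1, c0[j]] * tr
    hi <- base[r0, c0[j] + 1] * (1 - tr) + base[r0 + 1, c0[j] + 1] * tr
    out[, j] <- lo * (1 - tc[j]) + hi * tc[j]
  }
  out
}

# east-west ramp in [0,1], increasing eastward (column index)
east_ramp <- function(nr, nc) {
  matrix(rep((seq_len(nc) - 1) / max(nc - 1, 1), each = nr), nr, nc)
}

# one regional daily weather realisation shared by all stations: stations
# sample the same synoptic events, so their summaries differ by measurement
# noise and siting, not by independent climates. Wind has a spring windy
# season (scaled so the spring monthly mean 2 m wind sits a little above the
# 5 m/s sand-driving threshold, putting the annual weather factor near the
# ~20 kg/m scale of erosive drylands); precipitation is sparse and
# summer-weighted; snow comes as cold-season events.
simulate_regional_weather <- function(dates) {
  doy <- as.integer(format(dates, "%j"))
  n <- length(dates)
  season <- 1 + 1.8 * exp(-((doy - 105) / 45)^2)
  u10 <- stats::rweibull(n, shape = 5, scale = 3.2 * season)
  temp <- 8 + 16 * sin(2 * pi * (doy - 105) / 365) + stats::rnorm(n, sd = 2.5)
  wet <- stats::runif(n) < (0.06 + 0.10 * pmax(sin(2 * pi * (doy - 105) / 365), 0))
  precip <- ifelse(wet, stats::rgamma(n, shape = 1.2, scale = 4), 0)
  sr <- pmax(250 + 220 * sin(2 * pi * (doy - 105) / 365) + stats::rnorm(n, sd = 25), 30)
  cold <- temp < -2
  snow_event <- cold & stats::runif(n) < 0.25
  snow <- ifelse(snow_event, stats::rgamma(n, shape = 2, scale = 18), 0)
  data.frame(date = dates, u10 = u10, temp = temp, precip = precip,
             sr = sr, snow = snow)
}

# perturb the regional realisation for one station: a small multiplicative
# siting factor on wind and precipitation plus daily measurement noise
simulate_station <- function(id, x, y, elevation_km, regional, windiness = 1) {
  n <- nrow(regional)
  u10 <- pmax(regional$u10 * windiness + stats::rnorm(n, sd = 0.15), 0)
  temp <- regional$temp + stats::rnorm(1, sd = 0.5) + stats::rnorm(n, sd = 0.3)
  precip <- regional$precip * stats::runif(1, 0.9, 1.1)
  sr <- pmax(regional$sr + stats::rnorm(n, sd = 10), 20)
  snow <- regional$snow
  list(station_id = id, x = x, y = y,
       lon = 107 + x / 1e5, lat = 39 + y / 1e5,  # nominal geographic tags
       elevation_km = elevation_km,
       records = data.frame(date = regional$date, u10 = u10, temp = temp,
                            precip = precip, sr = sr, snow = snow))
}

#' Generate a fully synthetic study scene
#'
#' Builds every input layer the erosion pipeline needs on one shared grid,
#' with known structure so downstream stages can be tested without external
#' data: a gently sloping DEM, twelve monthly NDVI rasters whose annual mean
#' increases from west to east (so the actual erosion comes out high in the
#' west and the prevention service high in the east), closed soil-texture
#' fields (sand + silt + clay = 100), organic matter, carbonate, a soil-type
#' map cut from the texture, land-cover maps for two epochs with perturbed
#' class boundaries, population and GDP density surfaces, and daily weather
#' series at `n_stations` stations with a spring windy season. All
#' randomness flows from the single `seed`.
#'
#' @param nrows,ncols Grid dimensions (>= 4).
#' @param cellsize_m Cell size (m), default 1000.
#' @param n_stations Number of weather stations (>= 1).
#' @param years Number of simulated years (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @param n_soil_classes Soil-type classes cut from the sand field.
#' @return List of class `synthetic_scene` with elements `grid`, `dem`,
#'   `ndvi_monthly` (list of 12), `sand_pct`, `silt_pct`, `clay_pct`,
#'   `om_pct`, `caco3_pct`, `soil_type`, `landcover_t0`, `landcover_t1`,
#'   `pop_density`, `gdp_density`, `stations`, `truth`.
#' @export
generate_scene <- function(nrows, ncols, cellsize_m = 1000, n_stations = 5,
                           years = 1, seed = 1, n_soil_classes = 5) {
  if (nrows < 4 || ncols < 4) stop("nrows and ncols must be >= 4")
  if (n_stations < 1) stop("need at least one station")
  if (years < 1) stop("years must be >= 1")
  set.seed(as.integer(seed))
  grid <- grid_spec(nrows, ncols, cellsize_m)
  ramp <- east_ramp(nrows, ncols)

  # gentle relief: a few metres of elevation change per km, so ridge
  # roughness stays in the sub-centimetre-to-centimetre range of sandy plains
  dem <- 1000 + 60 * smooth_field(nrows, ncols, coarse = 4, sd = 0.5) +
    40 * (1 - ramp)
  dem <- pmin(pmax(dem, 900), 1600)

  # texture: sandy in the west, somewhat loamier in the east; closed to 100%.
  # The gradient is kept mild so the vegetation contrast, not the soil,
  # dominates the east-west pattern of the prevention service
  sand_raw <- 80 - 6 * ramp + 4 * smooth_field(nrows, ncols, coarse = 6)
  sand_raw <- pmin(pmax(sand_raw, 30), 95)
  silt_share <- 0.62 + 0.08 * smooth_field(nrows, ncols, coarse = 6, sd = 0.5)
  silt_share <- pmin(pmax(silt_share, 0.3), 0.85)
  rest <- 100 - sand_raw
  silt <- rest * silt_share
  clay <- rest - silt
  clay <- pmax(clay, 1)                 # keep Sa/Cl finite
  tot <- sand_raw + silt + clay
  sand <- sand_raw * 100 / tot; silt <- silt * 100 / tot; clay <- clay * 100 / tot
  om <- pmax(0.2 + 1.0 * ramp + 0.3 * smooth_field(nrows, ncols, coarse = 6), 0.05)
  caco3 <- pmax(1 + 2 * smooth_field(nrows, ncols, coarse = 6, sd = 0.5), 0.1)

  soil_type <- discretize(sand, method = "quantile", k = n_soil_classes,
                          source = "soil_type")$labels
  storage.mode(soil_type) <- "integer"

  # NDVI: the western third is bare desert core (flat, near-soil NDVI); cover
  # then rises convexly to the east, with a summer-peaked seasonal cycle
  ramp_eff <- pmax((ramp - 0.35) / 0.65, 0)
  ndvi_base <- 0.07 + 0.5 * ramp_eff^1.3 + 0.02 * smooth_field(nrows, ncols, coarse = 6)
  ndvi_monthly <- lapply(1:12, function(m) {
    seas <- 0.55 + 0.45 * sin(2 * pi * (m - 4.5) / 12 + pi / 2) # peak ~ July
    v <- ndvi_base * seas + stats::rnorm(1, sd = 0.01)
    pmin(pmax(v, -1), 1)
  })

  # land cover from annual NDVI; epoch 1 perturbs the thresholds so the
  # transition matrix is nontrivial (some desert greens into grassland)
  ndvi_mean <- Reduce(`+`, ndvi_monthly) / 12
  cut_lc <- function(v, th) {
    lc <- matrix(1L, nrows, ncols)            # 1 desert
    lc[v >= th[1]] <- 2L                      # 2 grassland
    lc[v >= th[2]] <- 3L                      # 3 cropland
    lc[v >= th[3]] <- 4L                      # 4 forest
    lc
  }
  landcover_t0 <- cut_lc(ndvi_mean, c(0.10, 0.20, 0.28))
  landcover_t1 <- cut_lc(ndvi_mean + 0.02 * smooth_field(nrows, ncols, 5) + 0.015,
                         c(0.10, 0.20, 0.28))

  pop <- exp(1 + 2 * ramp + 0.4 * smooth_field(nrows, ncols, coarse = 5))
  gdp <- pop * exp(0.3 * smooth_field(nrows, ncols, coarse = 5))

  dates <- seq(as.Date("2001-01-01"),
               as.Date(sprintf("%d-12-31", 2000 + years)), by = "day")
  ext_x <- ncols * cellsize_m; ext_y <- nrows * cellsize_m
  sx <- stats::runif(n_stations, 0.05, 0.95) * ext_x
  sy <- stats::runif(n_stations, 0.05, 0.95) * ext_y
  regional <- simulate_regional_weather(dates)
  stations <- lapply(seq_len(n_stations), function(i) {
    # mild siting spread around a uniform regional climate: the east-west
    # contrast in the service comes from vegetation, not a wind gradient
    simulate_station(sprintf("st%02d", i), sx[i], sy[i],
                     elevation_km = 1.0 + 0.4 * stats::runif(1),
                     regional = regional,
                     windiness = stats::runif(1, 0.98, 1.02))
  })

  structure(list(
    grid = grid, dem = dem, ndvi_monthly = ndvi_monthly,
    sand_pct = sand, silt_pct = silt, clay_pct = clay,
    om_pct = om, caco3_pct = caco3, soil_type = soil_type,
    landcover_t0 = landcover_t0, landcover_t1 = landcover_t1,
    pop_density = pop, gdp_density = gdp, stations = stations,
    truth = list(seed = seed, dominant_driver = "soil_type",
                 n_soil_classes = n_soil_classes)
  ), class = "synthetic_scene")
}

#' Plant a response with a known variance decomposition on given strata
#'
#' Draws one mean per stratum and rescales the resulting cell-level effect
#' vector so its population variance equals `between_var` exactly, then adds
#' independent cell noise N(0, `noise_var`). The geodetector q of the
#' response against these strata therefore concentrates on
#' between_var / (between_var + noise_var) — an analytic oracle for
#' driver-attribution tests. With only a handful of classes, rescaling (as
#' opposed to drawing means from N(0, between_var) and stopping there) is
#' what makes the planted ratio hold per realisation rather than merely in
#' expectation over class-mean draws.
#'
#' @param strata Integer class matrix/vector (or `strata_map`) with >= 2
#'   classes, each holding >= 2 cells.
#' @param between_var Variance of the stratum means (>= 0).
#' @param noise_var Variance of the within-stratum noise (>= 0).
#' @param seed Integer seed.
#' @return Numeric response, same shape as the strata labels.
#' @export
plant_driver_response <- function(strata, between_var, noise_var, seed = 1) {
  if (between_var < 0 || noise_var < 0) stop("variances must be >= 0")
  s <- if (inherits(strata, "strata_map")) strata$labels else strata
  sv <- as.vector(s)
  tab <- table(sv[!is.na(sv)])
  if (length(tab) < 2) stop("degenerate strata: need >= 2 classes")
  if (any(tab < 2)) stop("degenerate strata: every class needs >= 2 cells")
  set.seed(as.integer(seed))
  cls <- as.integer(names(tab))
  mu <- stats::rnorm(length(cls))
  eff <- mu[match(sv, cls)]
  if (between_var > 0) {
    ctr <- eff - mean(eff, na.rm = TRUE)
    v <- mean(ctr^2, na.rm = TRUE)
    if (v == 0) stop("degenerate effect draw: identical class means")
    eff <- ctr / sqrt(v) * sqrt(between_var)
  } else {
    eff <- 0 * eff
  }
  resp <- eff + stats::rnorm(length(sv), sd = sqrt(noise_var))
  out <- s
  out[] <- resp
  storage.mode(out) <- "double"
  out
}

#' Write a scene to a directory of plain-text layers
#'
#' One ASCII-grid file per raster layer, one CSV per station and a CSV
#' manifest, so a scene can be round-tripped through the on-disk formats.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- scene$grid
  layers <- c("dem", "sand_pct", "silt_pct", "clay_pct", "om_pct",
              "caco3_pct", "soil_type", "landcover_t0", "landcover_t1",
              "pop_density", "gdp_density")
  for (nm in layers)
    write_raster(matrix(as.numeric(scene[[nm]]), g$nrows, g$ncols),
                 g, file.path(dir, paste0(nm, ".asc")))
  for (m in 1:12)
    write_raster(scene$ndvi_monthly[[m]], g,
                 file.path(dir, sprintf("ndvi_%02d.asc", m)))
  st_rows <- lapply(scene$stations, function(s) {
    utils::write.csv(s$records,
                     file.path(dir, paste0(s$station_id, ".csv")),
                     row.names = FALSE)
    data.frame(station_id = s$station_id, x = s$x, y = s$y,
               lon = s$lon, lat = s$lat, elevation_km = s$elevation_km,
               file = paste0(s$station_id, ".csv"))
  })
  utils::write.csv(do.call(rbind, st_rows),
                   file.path(dir, "stations.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir Directory produced by [write_scene()].
#' @return A `synthetic_scene` (without the `truth` record, which is not
#'   persisted).
#' @export
read_scene <- function(dir) {
  rd <- function(nm) read_raster(file.path(dir, paste0(nm, ".asc")))
  first <- rd("dem")
  g <- first$grid
  get <- function(nm) {
    r <- rd(nm)
    check_aligned(g, r$grid, sprintf("dem and %s", nm))
    r$values
  }
  man <- utils::read.csv(file.path(dir, "stations.csv"),
                         stringsAsFactors = FALSE)
  stations <- lapply(seq_len(nrow(man)), function(i) {
    rec <- utils::read.csv(file.path(dir, man$file[i]),
                           stringsAsFactors = FALSE)
    rec$date <- as.Date(rec$date)
    list(station_id = man$station_id[i], x = man$x[i], y = man$y[i],
         lon = man$lon[i], lat = man$lat[i],
         elevation_km = man$elevation_km[i], records = rec)
  })
  as_int <- function(m) { storage.mode(m) <- "integer"; m }
  structure(list(
    grid = g, dem = first$values,
    ndvi_monthly = lapply(1:12, function(m) get(sprintf("ndvi_%02d", m))),
    sand_pct = get("sand_pct"), silt_pct = get("silt_pct"),
    clay_pct = get("clay_pct"), om_pct = get("om_pct"),
    caco3_pct = get("caco3_pct"),
    soil_type = as_int(get("soil_type")),
    landcover_t0 = as_int(get("landcover_t0")),
    landcover_t1 = as_int(get("landcover_t1")),
    pop_density = get("pop_density"), gdp_density = get("gdp_density"),
    stations = stations, truth = NULL
  ), class = "synthetic_scene")
}
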