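#' RWEQ factor equations
#'
#' Scalar (vectorised) forms of the five RWEQ controlling factors and their
#' meteorological precursors. All functions accept vectors or matrices and
#' return objects of the same shape, so a raster layer can be pushed through
#' unchanged; `NA` inputs propagate to `NA`.
#'
#' @name rweq-factors
NULL

#' Convert wind speed to 2 m height
#'
#' FAO logarithmic-profile conversion of a wind speed measured at height `z`
#' (typically the 10 m anemometer standard) to the 2 m height the erosion
#' model requires: u2 = u_z * 4.87 / ln(67.8 z - 5.42).
#'
#' @param u_z Wind speed at height `z` (m/s, >= 0).
#' @param z Measurement height (m); must satisfy 67.8 z - 5.42 > 1 so the
#'   profile is defined and positive.
#' @return Wind speed at 2 m (m/s).
#' @export
convert_wind_height <- function(u_z, z = 10) {
  if (any(z <= 5.42 / 67.8)) stop("height z makes log argument non-positive")
  if (any(u_z < 0, na.rm = TRUE)) stop("wind speed must be >= 0")
  u_z * 4.87 / log(67.8 * z - 5.42)
}

#' Air density from altitude and temperature
#'
#' rho = 348.0 (1.013 - 0.1183 EL + 0.0048 EL^2) / T, with altitude EL in km
#' and absolute temperature T in kelvin.
#'
#' @param EL Altitude (km).
#' @param T_k Absolute temperature (K, > 0).
#' @return Air density (kg/m^3).
#' @export
air_density <- function(EL, T_k) {
  if (any(T_k <= 0, na.rm = TRUE)) stop("absolute temperature must be > 0")
  348.0 * (1.013 - 0.1183 * EL + 0.0048 * EL^2) / T_k
}

#' Wind field intensity factor
#'
#' Wf = u2 (u2 - u1)^2 Nd for mean 2 m wind u2 above the sand-driving
#' threshold u1 (default 5 m/s); below the threshold no sand moves and Wf is
#' zero (the squared term alone would be positive either side of u1).
#'
#' @param u2 Monthly mean 2 m wind speed (m/s).
#' @param u1 Sand-driving threshold wind speed (m/s).
#' @param Nd Number of days in the period with daily 2 m wind above `u1`
#'   (>= 0).
#' @return Wind field intensity (m^3/s^3).
#' @export
wind_intensity_factor <- function(u2, u1 = 5, Nd) {
  if (any(Nd < 0, na.rm = TRUE)) stop("Nd must be >= 0")
  ifelse(u2 > u1, u2 * (u2 - u1)^2 * Nd, 0)
}

#' Soil wetness factor
#'
#' SW = (ETp - (R + I) Rd / Nd) / ETp, clamped to \[0, 1\]: moisture
#' suppression of erosion cannot exceed total suppression, and very wet
#' months would otherwise go negative.
#'
#' @param ETp Potential evapotranspiration over the period (mm, > 0).
#' @param R Precipitation over the period (mm).
#' @param I Irrigation over the period (mm); defaults to 0 where no
#'   irrigation data exist.
#' @param Rd Number of wet (rain or irrigation) days.
#' @param Nd_period Days in the period.
#' @return Dimensionless wetness factor in \[0, 1\].
#' @export
soil_wetness_factor <- function(ETp, R, I = 0, Rd, Nd_period) {
  if (any(ETp <= 0, na.rm = TRUE)) stop("ETp must be > 0")
  sw <- (ETp - (R + I) * Rd / Nd_period) / ETp
  pmin(pmax(sw, 0), 1)
}

#' Snow cover factor
#'
#' SD = 1 - P(Hsnow > 25.4 mm): the fraction of days the surface is not
#' shielded by a deep (> 1 inch) snowpack.
#'
#' @param snow_depths Daily snow depths (mm), non-empty.
#' @param threshold Shielding depth (mm), default 25.4.
#' @return Dimensionless snow factor in \[0, 1\].
#' @export
snow_factor <- function(snow_depths, threshold = 25.4) {
  if (length(snow_depths) == 0) stop("empty snow depth series")
  1 - mean(snow_depths > threshold, na.rm = TRUE)
}

#' Potential evapotranspiration from radiation and temperature
#'
#' Standard RWEQ form ETp = 0.0162 (SR / 58.5) (DT + 17.8), for use when a
#' gridded ETp product is not supplied directly.
#'
#' @param SR Total solar radiation over the period (cal/cm^2).
#' @param DT Mean air temperature over the period (deg C).
#' @return Potential evapotranspiration (mm); floored at 0.
#' @export
potential_evapotranspiration <- function(SR, DT) {
  pmax(0.0162 * (SR / 58.5) * (DT + 17.8), 0)
}

#' Monthly climate summaries from a daily station record
#'
#' Collapses a daily weather table into the per-month quantities the weather
#' factor needs: mean 2 m wind, count of sand-driving days, precipitation and
#' wet-day count, ETp (computed from radiation and temperature unless an
#' `etp` column is present), deep-snow probability and air density.
#'
#' @param records Data frame with columns `date` (Date), `u10` (m/s wind at
#'   `wind_height`), `temp` (deg C), `precip` (mm/day), `sr` (cal/cm^2/day),
#'   `snow` (mm snow depth).
#' @param elevation_km Station altitude (km) for the air-density term.
#' @param u1 Sand-driving wind threshold at 2 m (m/s).
#' @param wind_height Height of the wind record (m), converted to 2 m.
#' @param wet_day_mm Precipitation defining a wet day (mm), default 0.1.
#' @return Data frame with one row per calendar month present: `year`,
#'   `month`, `days`, `u2_mean`, `Nd`, `R`, `Rd`, `ETp`, `P_snow`, `SD`,
#'   `rho`.
#' @export
monthly_climate_summary <- function(records, elevation_km,
                                    u1 = 5, wind_height = 10,
                                    wet_day_mm = 0.1) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  need <- c("date", "u10", "temp", "precip", "sr", "snow")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  u2 <- convert_wind_height(records$u10, wind_height)
  key <- format(records$date, "%Y-%m")
  split_idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(names(split_idx), function(k) {
    i <- split_idx[[k]]
    days <- length(i)
    sr_total <- sum(records$sr[i])
    dt_mean <- mean(records$temp[i])
    etp <- if ("etp" %in% names(records)) sum(records$etp[i])
           else potential_evapotranspiration(sr_total, dt_mean)
    psnow <- mean(records$snow[i] > 25.4)
    data.frame(
      year = as.integer(substr(k, 1, 4)), month = as.integer(substr(k, 6, 7)),
      days = days,
      u2_mean = mean(u2[i]),
      Nd = sum(u2[i] > u1),
      R = sum(records$precip[i]),
      Rd = sum(records$precip[i] >= wet_day_mm),
      ETp = max(etp, 1e-6),
      P_snow = psnow,
      SD = 1 - psnow,
      rho = air_density(elevation_km, mean(dt_mean) + 273.15)
    )
  })
  do.call(rbind, rows)
}

#' Weather factor from monthly summaries
#'
#' WF = sum over months of Wf * (rho / g) * SW * SD, in kg/m. Months with no
#' sand-driving days contribute nothing; the per-month terms are additive so
#' the period total is the sum of its months.
#'
#' @param monthlies Data frame as returned by [monthly_climate_summary()].
#' @param u1 Sand-driving wind threshold (m/s).
#' @param g Gravitational acceleration (m/s^2).
#' @return Total weather factor over the summarised period (kg/m, >= 0).
#' @export
weather_factor <- function(monthlies, u1 = 5, g = 9.8) {
  stopifnot(is.data.frame(monthlies), nrow(monthlies) > 0)
  need <- c("u2_mean", "Nd", "R", "Rd", "ETp", "SD", "rho", "days")
  if (!all(need %in% names(monthlies)))
    stop("monthlies must have columns: ", paste(need, collapse = ", "))
  wf <- wind_intensity_factor(monthlies$u2_mean, u1, monthlies$Nd)
  sw <- soil_wetness_factor(monthlies$ETp, monthlies$R, 0,
                            monthlies$Rd, monthlies$days)
  sum(wf * (monthlies$rho / g) * sw * monthlies$SD)
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Cell value = sum(w_i v_i) / sum(w_i) with w_i = d_i^-power over the `k`
#' nearest stations. A cell whose centre coincides with a station takes that
#' station's value exactly.
#'
#' @param stations Data frame with columns `x`, `y` (projected m) and
#'   `value`.
#' @param grid Target `grid_spec`.
#' @param power Distance-decay exponent (default 2).
#' @param k Number of nearest stations used; default all.
#' @return Numeric matrix on `grid`.
#' @export
idw_interpolate <- function(stations, grid, power = 2, k = nrow(stations)) {
  stopifnot(is.data.frame(stations))
  if (nrow(stations) == 0) stop("no stations supplied")
  if (k < 1 || k > nrow(stations)) stop("k must be between 1 and the station count")
  ctr <- cell_centers(grid)
  n <- grid$nrows * grid$ncols
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  # n x nstation distance matrix; grids here are small enough to hold it
  d <- sqrt(outer(px, stations$x, "-")^2 + outer(py, stations$y, "-")^2)
  out <- numeric(n)
  hit <- d < 1e-9
  at_station <- rowSums(hit) > 0
  if (any(at_station)) {
    first_hit <- apply(hit[at_station, , drop = FALSE], 1, which.max)
    out[at_station] <- stations$value[first_hit]
  }
  idx <- which(!at_station)
  if (length(idx)) {
    dsub <- d[idx, , drop = FALSE]
    if (k < nrow(stations)) {
      # zero out all but the k nearest weights per cell
      keep <- t(apply(dsub, 1, function(r) {
        kth <- sort(r, partial = k)[k]; r <= kth
      }))
      w <- ifelse(keep, dsub^(-power), 0)
    } else {
      w <- dsub^(-power)
    }
    out[idx] <- rowSums(w * matrix(stations$value, length(idx),
                                   nrow(stations), byrow = TRUE)) / rowSums(w)
  }
  matrix(out, grid$nrows, grid$ncols)
}

#' Soil erodibility factor
#'
#' EF = (29.9 + 0.31 Sa + 0.17 Si + 0.33 Sa/Cl - 2.59 OM - 0.95 CaCO3) / 100,
#' the erodible fraction of the topsoil from its texture, organic matter and
#' carbonate content. The leading constant defaults to the 29.9 used here;
#' `constant = 29.09` selects the canonical RWEQ coefficient.
#'
#' @param Sa,Si,Cl Sand, silt, clay content (%); `Cl` must be > 0 (cells
#'   with zero clay are returned as `NA`).
#' @param OM Organic matter (%).
#' @param CaCO3 Calcium carbonate (%).
#' @param constant Leading constant (29.9 or 29.09).
#' @return Dimensionless erodible fraction.
#' @export
erodibility_factor <- function(Sa, Si, Cl, OM, CaCO3, constant = 29.9) {
  bad <- !is.na(Cl) & Cl <= 0
  Clz <- ifelse(bad, NA_real_, Cl)
  if (any(bad) && length(Sa) == 1)
    stop("clay content must be > 0 (division by zero in Sa/Cl)")
  ef <- (constant + 0.31 * Sa + 0.17 * Si + 0.33 * (Sa / Clz) -
           2.59 * OM - 0.95 * CaCO3) / 100
  ef
}

#' Soil crust factor
#'
#' SCF = 1 / (1 + 0.0066 Cl^2 + 0.021 OM^2), in (0, 1]: clay and organic
#' matter promote crusting, which shields the surface.
#'
#' @param Cl Clay content (%, >= 0).
#' @param OM Organic matter (%, >= 0).
#' @return Dimensionless crust factor.
#' @export
crust_factor <- function(Cl, OM) {
  if (any(Cl < 0, na.rm = TRUE) || any(OM < 0, na.rm = TRUE))
    stop("clay and organic matter contents must be >= 0")
  1 / (1 + 0.0066 * Cl^2 + 0.021 * OM^2)
}

#' Fractional vegetation cover by pixel dichotomy
#'
#' Linear unmixing of NDVI between a bare-soil and a full-vegetation
#' endpoint: SC = (NDVI - NDVIsoil) / (NDVIveg - NDVIsoil), clipped to
#' \[0, 1\]. When the endpoints are not supplied they are taken as the 5th
#' and 95th percentiles of the layer's NDVI distribution.
#'
#' @param ndvi Numeric matrix (or vector) of NDVI values.
#' @param ndvi_soil,ndvi_veg Endpoint NDVI values; `ndvi_veg` must exceed
#'   `ndvi_soil`.
#' @return Fractional cover in \[0, 1\], same shape as `ndvi`.
#' @export
fractional_cover <- function(ndvi, ndvi_soil = NULL, ndvi_veg = NULL) {
  if (is.null(ndvi_soil)) ndvi_soil <- stats::quantile(ndvi, 0.05, na.rm = TRUE, names = FALSE)
  if (is.null(ndvi_veg)) ndvi_veg <- stats::quantile(ndvi, 0.95, na.rm = TRUE, names = FALSE)
  if (ndvi_veg <= ndvi_soil) stop("ndvi_veg must exceed ndvi_soil")
  sc <- (ndvi - ndvi_soil) / (ndvi_veg - ndvi_soil)
  pmin(pmax(sc, 0), 1)
}

#' Vegetation factor
#'
#' C = exp(ai * cover), with cover expressed in percent (SC * 100) under the
#' default `scale = "percent"`; `ai = -0.0438` per percent cover. With
#' fractional-scale cover the factor would barely leave 1, so the percent
#' convention is the default; `scale = "fraction"` preserves the literal
#' fraction reading.
#'
#' @param SC Fractional vegetation cover in \[0, 1\].
#' @param ai Suppression coefficient (per percent cover).
#' @param scale `"percent"` (default) or `"fraction"`.
#' @return Dimensionless vegetation factor in (0, 1] for `ai < 0`.
#' @export
vegetation_factor <- function(SC, ai = -0.0438, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  if (any(SC < 0 | SC > 1, na.rm = TRUE)) stop("SC must lie in [0, 1]")
  cover <- if (scale == "percent") SC * 100 else SC
  exp(ai * cover)
}

#' Ridge roughness from a DEM
#'
#' Smith-Carson ridge roughness: within a square focal window of half-width
#' `L` the elevation relief dH = max - min is found, then
#' Kr = 0.2 dH^2 / L with dH and L in metres, reported in centimetres.
#'
#' @param dem Elevation matrix (m).
#' @param grid `grid_spec` of the DEM.
#' @param L Relief length scale (m), default 1000.
#' @return Matrix of ridge roughness (cm), >= 0.
#' @export
ridge_roughness <- function(dem, grid, L = 1000) {
  if (L <= 0) stop("L must be > 0")
  r <- max(1L, as.integer(round(L / grid$cellsize)))
  nr <- nrow(dem); nc <- ncol(dem)
  kr <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    i0 <- max(1, i - r); i1 <- min(nr, i + r)
    for (j in seq_len(nc)) {
      j0 <- max(1, j - r); j1 <- min(nc, j + r)
      w <- dem[i0:i1, j0:j1]
      if (all(is.na(w))) next
      dh <- max(w, na.rm = TRUE) - min(w, na.rm = TRUE)
      kr[i, j] <- 0.2 * dh^2 / L * 100  # m -> cm
    }
  }
  kr[is.na(dem)] <- NA_real_
  kr
}

#' Surface roughness factor
#'
#' K' = exp(1.86 Kr - 2.41 Kr^e - 0.127 Crr) with ridge roughness Kr and
#' random roughness Crr in cm. The exponent `e` defaults to the 0.94 used
#' here; `exponent = 0.934` selects the canonical RWEQ value.
#'
#' @param Kr Ridge roughness (cm, >= 0).
#' @param Crr Random roughness (cm), default 0.
#' @param exponent Exponent on the Kr damping term.
#' @return Dimensionless roughness factor.
#' @export
roughness_factor <- function(Kr, Crr = 0, exponent = 0.94) {
  if (any(Kr < 0, na.rm = TRUE)) stop("Kr must be >= 0")
  exp(1.86 * Kr - 2.41 * Kr^exponent - 0.127 * Crr)
}

#' Assemble the five-factor stack for a scene
#'
#' Builds WF, EF, SCF, K' and C rasters on one grid: per-station weather
#' factors are interpolated by IDW, soil factors come from the texture
#' layers, roughness from the DEM and the vegetation factor from the annual
#' mean NDVI by pixel dichotomy.
#'
#' @param scene A `synthetic_scene` (or any list with the same layers).
#' @param config Pipeline configuration, see [default_config()].
#' @return A list of class `factor_stack` with elements `WF`, `EF`, `SCF`,
#'   `Kprime`, `C`, `SC` (cover, kept for diagnostics) and `grid`.
#' @export
build_factor_stack <- function(scene, config = default_config()) {
  fc <- config$factors
  st_wf <- vapply(scene$stations, function(s) {
    m <- monthly_climate_summary(s$records, s$elevation_km,
                                 u1 = fc$u1, wind_height = fc$wind_height,
                                 wet_day_mm = fc$wet_day_mm)
    weather_factor(m, u1 = fc$u1, g = fc$g)
  }, numeric(1))
  pts <- data.frame(x = vapply(scene$stations, `[[`, numeric(1), "x"),
                    y = vapply(scene$stations, `[[`, numeric(1), "y"),
                    value = st_wf)
  WF <- idw_interpolate(pts, scene$grid, power = fc$idw_power,
                        k = min(fc$idw_k, nrow(pts)))
  EF <- erodibility_factor(scene$sand_pct, scene$silt_pct, scene$clay_pct,
                           scene$om_pct, scene$caco3_pct,
                           constant = fc$ef_constant)
  SCF <- crust_factor(scene$clay_pct, scene$om_pct)
  Kr <- ridge_roughness(scene$dem, scene$grid, L = fc$L)
  Kp <- roughness_factor(Kr, Crr = fc$crr, exponent = fc$kprime_exponent)
  ndvi_mean <- Reduce(`+`, scene$ndvi_monthly) / length(scene$ndvi_monthly)
  SC <- fractional_cover(ndvi_mean)
  C <- vegetation_factor(SC, ai = fc$ai, scale = fc$cover_scale)
  structure(list(WF = WF, EF = EF, SCF = SCF, Kprime = Kp, C = C, SC = SC,
                 grid = scene$grid),
            class = "factor_stack")
}
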