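test_that("wind height conversion matches direct evaluation and handles edges", {
  expect_equal(convert_wind_height(10, 10), 10 * 4.87 / log(672.58),
               tolerance = 1e-12)
  expect_equal(convert_wind_height(10, 10), 7.4795, tolerance = 1e-4)
  expect_equal(convert_wind_height(0, 10), 0)
  # near-identity at 2 m: the profile is anchored there
  expect_equal(convert_wind_height(6, 2), 6, tolerance = 1e-3)
  expect_error(convert_wind_height(5, 0.01), "log argument")
  expect_error(convert_wind_height(-1, 10), ">= 0")
})

test_that("air density reproduces hand evaluations of the altitude polynomial", {
  expect_equal(air_density(0, 288.15), 348.0 * 1.013 / 288.15, tolerance = 1e-12)
  expect_equal(air_density(0, 288.15), 1.2234, tolerance = 1e-4)
  expect_equal(air_density(1.2, 280),
               348.0 * (1.013 - 0.1183 * 1.2 + 0.0048 * 1.44) / 280,
               tolerance = 1e-12)
  expect_equal(air_density(0, 348.0 * 1.013), 1.0)
  expect_error(air_density(0, -3), "> 0")
})

test_that("wind intensity factor is zero at and below the threshold, cubic above", {
  expect_equal(wind_intensity_factor(7, 5, 10), 280)
  expect_equal(wind_intensity_factor(5, 5, 30), 0)
  expect_equal(wind_intensity_factor(4, 5, 30), 0)
  expect_error(wind_intensity_factor(7, 5, -1), "Nd")
  # nondecreasing in u2 above threshold
  u <- seq(5, 12, by = 0.1)
  wf <- wind_intensity_factor(u, 5, 10)
  expect_true(all(diff(wf) >= 0))
})

test_that("soil wetness factor computes the ETp balance and clamps to [0,1]", {
  expect_equal(soil_wetness_factor(100, 0, 0, 0, 30), 1)
  expect_equal(soil_wetness_factor(100, 30, 0, 5, 30), 0.95)
  expect_equal(soil_wetness_factor(10, 200, 0, 20, 30), 0)
  expect_error(soil_wetness_factor(0, 10, 0, 1, 30), "ETp")
})

test_that("snow factor is the fraction of shallow-snow days", {
  expect_equal(snow_factor(rep(0, 30)), 1)
  expect_equal(snow_factor(c(rep(30, 3), rep(0, 27))), 0.9)
  expect_equal(snow_factor(rep(30, 10)), 0)
  expect_error(snow_factor(numeric(0)), "empty")
})

test_that("weather factor composes Wf, density, wetness and snow and is additive", {
  m1 <- data.frame(u2_mean = 7, Nd = 10, R = 30, Rd = 5, ETp = 100,
                   P_snow = 0, SD = 1, rho = 1.2234, days = 30)
  expect_equal(weather_factor(m1), 280 * (1.2234 / 9.8) * 0.95 * 1,
               tolerance = 1e-12)
  expect_equal(weather_factor(m1), 33.21, tolerance = 1e-3)
  calm <- m1; calm$Nd <- 0; calm$u2_mean <- 3
  expect_equal(weather_factor(calm), 0)
  expect_equal(weather_factor(rbind(m1, m1)), 2 * weather_factor(m1))
})

test_that("monthly climate summaries have coherent counts and bounds", {
  sc <- tiny_scene(seed = 3)
  rec <- sc$stations[[1]]$records
  m <- monthly_climate_summary(rec, sc$stations[[1]]$elevation_km)
  expect_equal(nrow(m), 12)
  expect_equal(sum(m$days), nrow(rec))
  expect_true(all(m$Nd <= m$days))
  expect_true(all(m$Rd <= m$days))
  expect_true(all(m$P_snow >= 0 & m$P_snow <= 1))
  expect_true(all(m$ETp > 0))
  expect_equal(sum(m$R), sum(rec$precip), tolerance = 1e-9)
})

test_that("ETp formula scales linearly with radiation", {
  expect_equal(potential_evapotranspiration(585, 10),
               0.0162 * 10 * 27.8, tolerance = 1e-12)
  expect_equal(potential_evapotranspiration(2 * 585, 10),
               2 * potential_evapotranspiration(585, 10))
  # floor: strongly negative temperatures cannot yield negative ETp
  expect_equal(potential_evapotranspiration(100, -30), 0)
})

test_that("IDW is exact at stations, bounded by station values, and averages symmetric pairs", {
  g <- grid_spec(5, 5, 1000)
  one <- data.frame(x = 2500, y = 2500, value = 7.5)
  expect_true(all(abs(idw_interpolate(one, g) - 7.5) < 1e-12))
  # station on a cell centre: that cell reproduces the value exactly
  st <- data.frame(x = c(500, 4500), y = c(2500, 2500), value = c(2, 4))
  out <- idw_interpolate(st, g)
  expect_equal(out[3, 1], 2)
  expect_equal(out[3, 5], 4)
  expect_equal(out[3, 3], 3)  # equidistant cell averages the pair
  expect_true(all(out >= 2 & out <= 4))
  expect_error(idw_interpolate(st[0, ], g), "no stations")
  expect_error(idw_interpolate(st, g, k = 5), "k must be")
})

test_that("erodibility factor matches hand evaluations and flags zero clay", {
  expect_equal(erodibility_factor(90, 5, 5, 0.3, 1), 0.62863, tolerance = 1e-5)
  expect_equal(erodibility_factor(0, 0, 100, 0, 0), 0.299, tolerance = 1e-12)
  expect_equal(erodibility_factor(50, 25, 25, 10, 10),
               (29.9 + 15.5 + 4.25 + 0.66 - 25.9 - 9.5) / 100,
               tolerance = 1e-12)
  expect_error(erodibility_factor(50, 25, 0, 1, 1), "clay")
  # raster mode: zero-clay cells become nodata rather than erroring
  out <- erodibility_factor(c(50, 50), c(25, 25), c(25, 0), c(1, 1), c(1, 1))
  expect_true(is.na(out[2]) && !is.na(out[1]))
  # canonical-constant switch shifts the factor by exactly the delta
  expect_equal(erodibility_factor(90, 5, 5, 0.3, 1, constant = 29.09),
               erodibility_factor(90, 5, 5, 0.3, 1) - 0.81 / 100,
               tolerance = 1e-12)
})

test_that("crust factor is in (0,1] and strictly decreasing in clay and organic matter", {
  expect_equal(crust_factor(0, 0), 1)
  expect_equal(crust_factor(5, 0.3), 1 / (1 + 0.0066 * 25 + 0.021 * 0.09),
               tolerance = 1e-12)
  expect_equal(crust_factor(100, 0), 1 / 67, tolerance = 1e-12)
  cl <- seq(0, 60, by = 1)
  expect_true(all(diff(crust_factor(cl, 1)) < 0))
  om <- seq(0, 10, by = 0.5)
  expect_true(all(diff(crust_factor(10, om)) < 0))
  expect_error(crust_factor(-1, 0), ">= 0")
})

test_that("fractional cover is linear between endpoints and clipped outside", {
  expect_equal(fractional_cover(0.1, 0.1, 0.8), 0)
  expect_equal(fractional_cover(0.45, 0.1, 0.8), 0.5)
  expect_equal(fractional_cover(0.9, 0.1, 0.8), 1)
  expect_equal(fractional_cover(-0.2, 0.1, 0.8), 0)
  expect_error(fractional_cover(0.5, 0.8, 0.1), "exceed")
  # percentile default endpoints: 5% of cells at 0, 5% at 1
  set.seed(1)
  v <- matrix(runif(400), 20, 20)
  sc <- fractional_cover(v)
  expect_equal(mean(sc == 0), 0.05, tolerance = 0.02)
  expect_equal(mean(sc == 1), 0.05, tolerance = 0.02)
})

test_that("vegetation factor decays exponentially in percent cover", {
  expect_equal(vegetation_factor(0), 1)
  expect_equal(vegetation_factor(0.5), exp(-0.0438 * 50), tolerance = 1e-12)
  expect_equal(vegetation_factor(1), exp(-4.38), tolerance = 1e-12)
  s <- seq(0, 1, by = 0.05)
  expect_true(all(diff(vegetation_factor(s)) < 0))
  expect_error(vegetation_factor(1.2), "\\[0, 1\\]")
  # literal fraction-scale switch barely leaves 1
  expect_equal(vegetation_factor(0.5, scale = "fraction"), exp(-0.0219),
               tolerance = 1e-12)
})

test_that("ridge roughness is zero on flat terrain and quadratic in relief", {
  g <- grid_spec(6, 6, 1000)
  expect_true(all(ridge_roughness(matrix(1000, 6, 6), g) == 0))
  # one 5 m bump: neighbouring windows see dH = 5 -> 0.5 cm
  dem <- matrix(1000, 6, 6); dem[3, 3] <- 1005
  kr <- ridge_roughness(dem, g, L = 1000)
  expect_equal(kr[3, 3], 0.2 * 25 / 1000 * 100, tolerance = 1e-12)
  expect_equal(kr[3, 3], 0.5)
  dem2 <- matrix(1000, 6, 6); dem2[3, 3] <- 1010
  expect_equal(ridge_roughness(dem2, g)[3, 3], 4 * kr[3, 3], tolerance = 1e-12)
})

test_that("roughness factor matches direct evaluation of the Smith-Carson form", {
  expect_equal(roughness_factor(0), 1)
  expect_equal(roughness_factor(1), exp(1.86 - 2.41), tolerance = 1e-12)
  expect_equal(roughness_factor(1), 0.5769, tolerance = 1e-4)
  expect_equal(roughness_factor(0.5), exp(0.93 - 2.41 * 0.5^0.94),
               tolerance = 1e-12)
  expect_error(roughness_factor(-0.1), ">= 0")
})

test_that("factor functions give identical results on rasters and per-cell loops", {
  set.seed(7)
  sa <- matrix(runif(30, 40, 90), 5, 6)
  si <- matrix(runif(30, 5, 30), 5, 6)
  cl <- pmax(100 - sa - si, 1)
  om <- matrix(runif(30, 0.1, 3), 5, 6)
  ca <- matrix(runif(30, 0.1, 5), 5, 6)
  ef <- erodibility_factor(sa, si, cl, om, ca)
  scf <- crust_factor(cl, om)
  for (idx in sample(30, 8)) {
    expect_equal(ef[idx], erodibility_factor(sa[idx], si[idx], cl[idx],
                                             om[idx], ca[idx]))
    expect_equal(scf[idx], crust_factor(cl[idx], om[idx]))
  }
})

test_that("factor stack on a synthetic scene satisfies the physical ranges", {
  sc <- tiny_scene(seed = 5)
  st <- build_factor_stack(sc)
  expect_true(all(st$WF >= 0))
  expect_true(all(st$EF > 0 & st$EF < 1))
  expect_true(all(st$SCF > 0 & st$SCF <= 1))
  expect_true(all(st$C > 0 & st$C <= 1))
  expect_true(all(st$SC >= 0 & st$SC <= 1))
  expect_true(same_grid(st$grid, sc$grid))
})
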