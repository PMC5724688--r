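# Independent solar-declination oracle: NOAA-style computation from the sun's
# apparent ecliptic longitude (different derivation from the package's
# Fourier-series formula).
noaa_declination <- function(day_of_year) {
  d <- day_of_year - 1
  g <- (357.529 + 0.98560028 * d) %% 360          # mean anomaly, deg
  q <- (280.459 + 0.98564736 * d) %% 360          # mean longitude, deg
  l <- q + 1.915 * sin(g * pi / 180) + 0.020 * sin(2 * g * pi / 180)
  e <- 23.439 - 0.00000036 * d                    # obliquity, deg
  asin(sin(e * pi / 180) * sin(l * pi / 180)) * 180 / pi
}

test_that("solar course reproduces standard geometry and daylength", {
  # equator at the March equinox: overhead sun at noon
  # (0.96 h steps place one step centre exactly at solar noon)
  eq <- solar_course(0, 80, 0.96)
  expect_lt(min(eq$zenith), 1.5)
  # night steps carry zero flux
  sc <- solar_course(31, 235, 0.5)
  night <- sc$zenith >= 90
  expect_true(all(sc$direct_ppfd[night] == 0))
  expect_true(all(sc$diffuse_ppfd[night] == 0))
  # symmetric about solar noon
  expect_equal(sc$zenith, rev(sc$zenith), tolerance = 1e-9)
  # noon zenith against the independent ephemeris oracle
  noon_zen <- min(solar_course(31, 235, 0.96)$zenith)
  expect_lt(abs(noon_zen - (31 - noaa_declination(235))), 0.5)
  # daylit step count consistent with the daylength formula
  decl <- noaa_declination(235) * pi / 180
  daylength <- 2 * acos(-tan(31 * pi / 180) * tan(decl)) * 180 / pi / 15
  expect_lt(abs(sum(sc$above_ppfd > 0) * 0.5 - daylength), 1)
  # longer day at 45 N than 18 N on DOY 235
  expect_gt(sum(solar_course(45, 235)$above_ppfd > 0),
            sum(solar_course(18, 235)$above_ppfd > 0))
})

test_that("single-interaction energy splits match facet optics", {
  m <- single_facet_canopy(area = 0.04, height = 0.5)
  sun <- solar_state(0, 180, 1000, 0)
  tr <- trace_canopy(m, leaf_optics(0.05, 0.05), sun, rays_per_m2 = 2e5,
                     seed = 1)
  inc <- stats::weighted.mean(tr$incident, m$facet_area)
  abs_ <- stats::weighted.mean(tr$absorbed, m$facet_area)
  expect_equal(inc, 1000, tolerance = 0.05)
  expect_equal(abs_ / inc, 0.9, tolerance = 1e-9)
})

test_that("transmission through a full-cover layer follows transmittance", {
  m <- stacked_facets_canopy(2, area = 1, top = 0.6, bottom = 0.55,
                             ground_side = 1)
  sun <- solar_state(0, 180, 1000, 0)
  tr <- trace_canopy(m, leaf_optics(0.1, 0.1), sun, rays_per_m2 = 1e5,
                     max_bounces = 1, seed = 2)
  upper <- stats::weighted.mean(tr$incident[1:2], m$facet_area[1:2])
  lower <- stats::weighted.mean(tr$incident[3:4], m$facet_area[3:4])
  expect_equal(upper, 1000, tolerance = 1e-6)   # full cover: deterministic
  expect_equal(lower, 100, tolerance = 0.03)    # 0.1 * I, Monte-Carlo error
})

test_that("the tracer conserves energy and is seed-reproducible", {
  rc <- random_canopy(n_facets = 800, lai = 2, seed = 9)
  sun <- solar_state(30, 150, 1200, 200)
  tr <- trace_canopy(rc, leaf_optics(0.08, 0.07), sun, rays_per_m2 = 5e4,
                     seed = 4)
  ledger <- (sum(tr$absorbed_power) + tr$soil_absorbed + tr$escaped +
               tr$residual) / tr$incoming
  expect_equal(ledger, 1, tolerance = 1e-9)  # deterministic splitting
  tr2 <- trace_canopy(rc, leaf_optics(0.08, 0.07), sun, rays_per_m2 = 5e4,
                      seed = 4)
  expect_identical(tr$incident, tr2$incident)
})

test_that("facet means are unbiased in ray density", {
  rc <- random_canopy(n_facets = 500, lai = 1.5, seed = 21)
  sun <- solar_state(20, 180, 1000, 150)
  op <- leaf_optics(0.08, 0.07)
  t1 <- trace_canopy(rc, op, sun, rays_per_m2 = 2e4, seed = 5)
  t2 <- trace_canopy(rc, op, sun, rays_per_m2 = 8e4, seed = 6)
  tot1 <- sum(t1$absorbed_power) / t1$incoming
  tot2 <- sum(t2$absorbed_power) / t2$incoming
  expect_equal(tot1, tot2, tolerance = 0.02)
})

test_that("diurnal light on a lone horizontal facet follows the sky model", {
  m <- single_facet_canopy(area = 0.09, height = 0.3)
  f <- diurnal_light(m, leaf_optics(0.05, 0.05), latitude = 31,
                     day_of_year = 235, time_step_h = 2, rays_per_m2 = 5e4,
                     seed = 3)
  day <- f$above_ppfd > 0
  # closed form for a horizontal facet: incident = global horizontal PPFD
  inc <- colMeans(f$incident[, day, drop = FALSE])
  expect_equal(inc, f$above_ppfd[day], tolerance = 0.05)
  # zero-LAI canopy: soil receives everything
  empty <- random_canopy(n_facets = 1, lai = 1e-6, seed = 1)
  sun <- solar_state(0, 180, 1000, 0)
  tr <- trace_canopy(empty, leaf_optics(0.1, 0.1), sun, rays_per_m2 = 2e4,
                     seed = 1)
  expect_gt(tr$soil_absorbed / tr$incoming, 0.999)
})

test_that("extinction fitting recovers a synthetic Beer profile", {
  rc <- random_canopy(n_facets = 1200, lai = 3, seed = 13)
  ord <- order(rc$facet_centroid[, 3], decreasing = TRUE)
  area <- rc$facet_area[ord]
  cl <- (cumsum(area) - area / 2) / rc$ground_area
  incident <- numeric(length(ord))
  incident[ord] <- 1000 * exp(-0.5 * cl)
  field <- list(times = 12, incident = matrix(incident),
                absorbed = matrix(incident * 0.9), above_ppfd = 1000,
                time_step_h = 0.5)
  class(field) <- "light_field"
  ef <- fit_extinction(field, rc, 1, measure = "incident")
  expect_equal(ef$k, 0.5, tolerance = 0.02)
  expect_gt(ef$r_squared, 0.999)
})

test_that("extinction strengthens with leaf absorbance (traced field)", {
  rc <- random_canopy(n_facets = 1500, lai = 2.5, seed = 17)
  sun1 <- data.frame(hour = 12, zenith = 0, azimuth = 180,
                     direct_ppfd = 1000, diffuse_ppfd = 0, above_ppfd = 1000)
  k_for <- function(optics) {
    f <- diurnal_light(rc, optics, course = sun1, rays_per_m2 = 5e4,
                       seed = 8)
    fit_extinction(f, rc, 1)$k
  }
  k_dark <- k_for(leaf_optics(0.05, 0.05))   # absorbance 0.90
  k_pale <- k_for(leaf_optics(0.17, 0.18))   # absorbance 0.65
  # spherical leaf-angle canopy, zenith 0: turbid-medium oracle k ~ G/cos(0)
  expect_lt(abs(k_dark - 0.5) / 0.5, 0.15)
  expect_lt(k_pale, k_dark)
})

test_that("layer means follow the cumulative-LAI binning definition", {
  st <- stacked_facets_canopy(10, area = 0.04, top = 1, bottom = 0.1)
  nt <- 1
  uni <- list(times = 12, incident = matrix(500, 20, nt),
              absorbed = matrix(450, 20, nt), above_ppfd = 1000,
              time_step_h = 0.5)
  class(uni) <- "light_field"
  lm_u <- layer_means(uni, st, 0.2, time_index = 1)
  expect_equal(unname(lm_u["top"]), unname(lm_u["bottom"]))
  # distinct per-layer values: fraction 0.2 of 10 equal layers = 2 layers
  vals <- rep(seq(100, 1000, length.out = 10), each = 2)
  fld <- list(times = 12, incident = matrix(vals, 20, 1),
              absorbed = matrix(vals * 0.9, 20, 1), above_ppfd = 1000,
              time_step_h = 0.5)
  class(fld) <- "light_field"
  lm_f <- layer_means(fld, st, 0.2, time_index = 1)
  # facets are built top-down, so the top two layers carry 100 and 200
  expect_equal(unname(lm_f["top"]), 150)
  expect_equal(unname(lm_f["bottom"]), 950)
})

test_that("lower absorbance brightens the bottom canopy layer", {
  base <- cached_base()
  mesh <- base$mesh
  course <- data.frame(hour = 12, zenith = 10, azimuth = 180,
                       direct_ppfd = 1500, diffuse_ppfd = 300,
                       above_ppfd = 1500 * cos(10 * pi / 180) + 300)
  f_dark <- diurnal_light(mesh, leaf_optics(0.05, 0.05), course = course,
                          rays_per_m2 = 2e4, seed = 31)
  f_pale <- diurnal_light(mesh, leaf_optics(0.18, 0.18), course = course,
                          rays_per_m2 = 2e4, seed = 31)
  lm_dark <- layer_means(f_dark, mesh, 0.2, 1)
  lm_pale <- layer_means(f_pale, mesh, 0.2, 1)
  expect_gt(lm_pale["bottom"], lm_dark["bottom"])
})

test_that("light-field CSV export is long-format and complete", {
  m <- single_facet_canopy()
  f <- diurnal_light(m, leaf_optics(0.05, 0.05), time_step_h = 6,
                     rays_per_m2 = 1e4, seed = 2)
  p <- tempfile(fileext = ".csv")
  write_light_field(f, p)
  df <- utils::read.csv(p)
  expect_named(df, c("facet_id", "time", "incident_ppfd", "absorbed_ppfd"))
  expect_equal(nrow(df), 2 * length(f$times))
})
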