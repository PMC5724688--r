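test_that("configuration round-trips through YAML with validation", {
  cfg <- default_config()
  cfg$site$latitude <- 40
  cfg$trace$rays_per_m2 <- 1234
  p <- tempfile(fileext = ".yaml")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(unclass(back), unclass(cfg))
  writeLines("bogus_block:\n  a: 1", p)
  expect_error(read_config(p), "unknown config block")
})

test_that("the pipeline result satisfies its own conservation identities", {
  base <- cached_base()
  res <- canophot:::pipeline_scenario(base, 1, "lhc_only")
  # A_c equals the ground-normalised per-facet integral
  expect_equal(res$a_c_daily,
               sum(res$per_facet$daily_a * res$per_facet$area) /
                 base$mesh$ground_area, tolerance = 1e-12)
  # NUE is definitionally A_c over canopy photosynthetic N
  expect_equal(res$nue, res$a_c_daily / res$canopy_photo_n)
  # canopy N likewise area-consistent
  expect_equal(res$canopy_photo_n,
               sum(res$per_facet$photo_n * res$per_facet$area) /
                 base$mesh$ground_area, tolerance = 1e-12)
  # default canopy hits the configured mean chlorophyll
  expect_equal(res$mean_chl, 494.7, tolerance = 0.01)
})

test_that("the pipeline is reproducible from (config, seed)", {
  cfg <- small_config()
  cfg$canopy$plants_x <- 1; cfg$canopy$plants_y <- 1
  cfg$canopy$tillers <- 3
  cfg$site$time_step_h <- 3
  r1 <- run_pipeline(cfg, seed = 7)
  r2 <- run_pipeline(cfg, seed = 7)
  expect_identical(r1$a_c_daily, r2$a_c_daily)
  expect_identical(r1$per_facet, r2$per_facet)
})

test_that("a polar-night run is pure respiration", {
  cfg <- small_config()
  cfg$canopy$plants_x <- 1; cfg$canopy$plants_y <- 1
  cfg$canopy$tillers <- 3
  cfg$site$latitude <- -75
  cfg$site$day_of_year <- 172
  cfg$site$time_step_h <- 2
  res <- run_pipeline(cfg, seed = 3)
  kk <- kinetic_params()
  vc <- pmin(kk$kcat_rubisco * kk$rubisco_sites * res$pools$rubisco /
               kk$mw_rubisco * 1e6, kk$k_ce * res$pools$ce)
  expected <- -sum(kk$rd_frac * vc * res$per_facet$area) /
    sum(res$per_facet$area) * mesh_lai(canophot:::pipeline_base(cfg, 3)$mesh) *
    86400 * 1e-6
  expect_lt(res$a_c_daily, 0)
  expect_equal(res$a_c_daily, expected, tolerance = 1e-6)
})

test_that("chlorophyll sweep orderings match the scenario logic", {
  base <- cached_base()
  sw <- run_chl_sweep(small_config(), multipliers = c(0.4, 0.7, 1.0),
                      seed = 42, base = base)
  # self-comparison row is exactly zero
  ref_rows <- sw[sw$multiplier == 1, ]
  expect_true(all(ref_rows$d_a_c_pct == 0))
  expect_true(all(ref_rows$d_nue_pct == 0))
  # reinvested nitrogen always beats discarding it, below default chl
  for (m in c(0.4, 0.7)) {
    a_con <- sw$d_a_c_pct[sw$multiplier == m &
                            sw$strategy == "constant_total_n"]
    a_lhc <- sw$d_a_c_pct[sw$multiplier == m & sw$strategy == "lhc_only"]
    expect_gt(a_con, a_lhc)
  }
  # both strategies raise NUE at strong chlorophyll reduction
  expect_true(all(sw$d_nue_pct[sw$multiplier == 0.4] > 0))
})

test_that("reduced chlorophyll redistributes absorbed light downward", {
  base <- cached_base()
  ref <- canophot:::pipeline_scenario(base, 1, "lhc_only")
  red <- canophot:::pipeline_scenario(base, 0.4, "constant_total_n")
  d <- red$per_facet$daily_absorbed - ref$per_facet$daily_absorbed
  hi <- ref$per_facet$daily_absorbed
  top <- hi > stats::quantile(hi, 0.8)
  bot <- hi < stats::quantile(hi, 0.2)
  expect_lt(mean(d[top]), 0)   # bright leaves absorb less
  expect_gt(mean(d[bot]), 0)   # shaded leaves absorb more
})

test_that("architecture sweep spans the grid and tracks daylength", {
  cfg <- small_config()
  cfg$canopy$plants_x <- 1; cfg$canopy$plants_y <- 1
  cfg$canopy$tillers <- 4
  cfg$site$time_step_h <- 2
  cfg$trace$rays_per_m2 <- 4e3
  sweep <- run_architecture_sweep(cfg, angle_factors = 1,
                                  height_factors = 1,
                                  lai_factors = c(0.7, 1.3),
                                  latitudes = c(45, 18), seed = 2)
  expect_equal(nrow(sweep), 4)
  expect_named(sweep, c("angle", "height", "lai", "latitude", "a_c_default",
                        "a_c_reduced", "d_a_c_pct", "benefit"))
  # more daylit steps at 45 N than 18 N on DOY 235
  expect_gt(sum(solar_course(45, 235, 0.5)$above_ppfd > 0),
            sum(solar_course(18, 235, 0.5)$above_ppfd > 0))
})

test_that("report writes consistent tables and a usable manifest", {
  base <- cached_base()
  sw <- run_chl_sweep(small_config(), multipliers = c(0.5, 1.0),
                      strategies = "constant_total_n", seed = 42,
                      base = base)
  dir <- tempfile()
  paths <- report(sw, dir, config = small_config(), seed = 42)
  expect_true(all(file.exists(file.path(dir, c("chl_sweep.csv",
                                               "per_facet.csv",
                                               "manifest.json")))))
  per <- utils::read.csv(file.path(dir, "per_facet.csv"))
  tab <- utils::read.csv(file.path(dir, "chl_sweep.csv"))
  # one row per facet per scenario cell
  expect_equal(nrow(per), nrow(tab) * nrow(base$mesh$triangles))
  # sweep totals cross-check against per-facet integrals
  ground <- base$mesh$ground_area
  for (i in seq_len(nrow(tab))) {
    sub <- per[per$multiplier == tab$multiplier[i] &
                 per$strategy == tab$strategy[i], ]
    expect_equal(sum(sub$daily_a * sub$area) / ground, tab$a_c[i],
                 tolerance = 1e-3)
  }
  # manifest carries a config that round-trips
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 42)
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(man$config_yaml, cfg_file)
  expect_equal(unclass(read_config(cfg_file)), unclass(small_config()))
})
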