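# End-to-end pipeline: canopy -> diurnal light -> nitrogen profile ->
# per-leaf acclimation -> antenna/nitrogen scenario -> time-resolved leaf
# assimilation -> daily canopy CO2 uptake and nitrogen use efficiency.

#' Default simulation configuration
#'
#' A nested list mirroring the YAML config schema: `site` (latitude 31 N,
#' day of year 235, 0.5 h steps), `canopy` (3 x 3 plants at 20 plants m-2),
#' `chl` (mean 494.7 umol m-2, uniform distribution, multiplier 1),
#' `optics`, `nitrogen`, `acclimation` (photosynthetic fraction of leaf
#' nitrogen, frontier grid), `scenario` (nitrogen strategy) and `trace`
#' (ray density per m2 of plot, bounce limit, cutoff, soil reflectance).
#'
#' @return Object of class `canophot_config`.
#' @export
default_config <- function() {
  structure(list(
    site = list(latitude = 31, day_of_year = 235, time_step_h = 0.5),
    canopy = list(plants_x = 3, plants_y = 3, tillers = 11, segments = 5,
                  angle_factor = 1, height_factor = 1, lai_factor = 1),
    chl = list(mean = 494.7, distribution = "uniform", multiplier = 1.0),
    optics = list(a_max = 0.96, chl_ref = 494.7, abs_at_ref = 0.90,
                  r_share = 0.5),
    nitrogen = list(nla_flag = 1.6, n_b = 0.4, beta = 0.8, alpha = 0.45,
                    form = "power"),
    acclimation = list(photo_frac = 0.75, grid_size = 40),
    scenario = list(n_strategy = "lhc_only"),
    trace = list(rays_per_m2 = 2e4, max_bounces = 2, energy_cutoff = 0.01,
                 soil_reflectance = 0)),
    class = "canophot_config")
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `canophot_config`.
#' @return `read_config()` returns a `canophot_config` (defaults fill any
#'   omitted block); `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (blk in names(user)) {
    if (!blk %in% names(cfg)) stop("unknown config block: ", blk)
    for (key in names(user[[blk]])) {
      if (!key %in% names(cfg[[blk]]))
        stop("unknown config key: ", blk, "$", key)
      cfg[[blk]][[key]] <- user[[blk]][[key]]
    }
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_spec <- function(config) {
  cv <- config$canopy
  spec <- default_canopy_spec(cv$plants_x, cv$plants_y, cv$tillers,
                              as.integer(cv$segments))
  apply_architecture_factors(spec, cv$angle_factor, cv$height_factor,
                             cv$lai_factor)
}

config_optics <- function(config, chl) {
  ov <- config$optics
  optics_from_chl(chl, ov$a_max, ov$chl_ref, ov$abs_at_ref, ov$r_share)
}

# Vectorised per-facet acclimation: budgets (g N m-2) and the facet x time
# incident growth-light matrix.  Evaluates the frontier grid for all facets
# at once; strict > keeps the lowest-capacity split on ties.
acclimate_canopy <- function(budgets, incident, time_step_h, relations,
                             grid_size = 40, x_range = c(0.05, 0.95)) {
  f <- length(budgets)
  xs <- seq(x_range[1], x_range[2], length.out = grid_size)
  c1 <- rel_coef(relations, "rubisco")
  c4 <- rel_coef(relations, "psii")
  sh <- side_shares(relations)
  npu <- n_per_unit(relations$kinetics)
  dt_s <- time_step_h * 3600
  best_dc <- rep(-Inf, f); best_x <- numeric(f)
  best_pm <- numeric(f); best_phi <- numeric(f)
  for (x in xs) {
    rub <- x * budgets * sh$cap[["rubisco"]] / npu[["rubisco"]]
    psii <- (1 - x) * budgets * sh$ps[["psii"]] / npu[["psii"]]
    pm <- pmax(0.05, pmin(c1[["a"]] * rub + c1[["b"]],
                          pmax_psii_cap(psii, relations$kinetics)))
    phi <- pmin(0.1249, pmax(1e-4, c4[["a"]] * psii + c4[["b"]]))
    theta <- relations$theta
    dc <- numeric(f)
    for (t in seq_len(ncol(incident))) {
      q <- incident[, t]
      s <- phi * q + pm
      a <- (s - sqrt(pmax(0, s^2 - 4 * theta * phi * q * pm))) / (2 * theta)
      dc <- dc + a * dt_s
    }
    upd <- dc > best_dc
    best_dc[upd] <- dc[upd]; best_x[upd] <- x
    best_pm[upd] <- pm[upd]; best_phi[upd] <- phi[upd]
  }
  pools <- pools_at_split(best_x, budgets, relations)
  list(pools = pools, p_max = best_pm, phi = best_phi, x = best_x,
       daily_carbon = (best_dc - relations$r_d * 86400) * 1e-6)
}

# Stages shared by every scenario at one canopy/site: mesh, default-optics
# light field, Eq-3/4 nitrogen profile, linearised relations, and the
# acclimated default pools with antennas trimmed to the assigned
# default-chlorophyll field.
pipeline_base <- function(config, seed = 1L, relations = NULL) {
  stopifnot(inherits(config, "canophot_config"))
  kinetics <- kinetic_params()
  mesh <- build_canopy(config_spec(config), seed = seed)
  mode <- if (config$chl$distribution == "uniform") "uniform" else "profiled"
  mesh <- assign_chlorophyll(mesh, mode, config$chl$mean)
  optics <- config_optics(config, mesh$facet_chl)
  tv <- config$trace
  field <- diurnal_light(mesh, optics, config$site$latitude,
                         config$site$day_of_year, config$site$time_step_h,
                         rays_per_m2 = tv$rays_per_m2,
                         max_bounces = tv$max_bounces,
                         energy_cutoff = tv$energy_cutoff, seed = seed,
                         soil_reflectance = tv$soil_reflectance)
  np <- config$nitrogen
  nprof <- if (any(field$above_ppfd > 0)) {
    nitrogen_profile(field, mesh,
                     nitrogen_params(np$nla_flag, np$n_b, np$beta,
                                     np$alpha, np$form))
  } else {
    # polar-night degenerate case: no light gradient, nitrogen at the basal
    # level everywhere (the I_l -> 0 limit of the profile equation)
    structure(list(nla = rep(np$n_b, nrow(mesh$triangles)),
                   total_canopy_n = np$n_b * mesh_lai(mesh),
                   b = NA_real_, i_ratio = rep(0, nrow(mesh$triangles))),
              class = "nitrogen_profile")
  }
  if (is.null(relations)) relations <- calibrate_linear_relations(kinetics)
  budgets <- config$acclimation$photo_frac * nprof$nla
  daylit <- which(field$above_ppfd > 0)
  acc <- acclimate_canopy(budgets, field$incident[, daylit, drop = FALSE],
                          field$time_step_h, relations,
                          config$acclimation$grid_size)
  # pin each leaf's antenna to its assigned chlorophyll (chlorophyll sets
  # the LHC pools at the acclimated reaction-centre numbers)
  core <- kinetics$core_chl_psii * acc$pools$psii +
    kinetics$core_chl_psi * acc$pools$psi
  target <- pmax(mesh$facet_chl, core + 1e-6)
  pools <- modify_chlorophyll(acc$pools, target, "antenna_size", kinetics)
  list(config = config, seed = seed, kinetics = kinetics, mesh = mesh,
       field = field, nprofile = nprof, relations = relations,
       budgets = budgets, pools_default = pools, acclimation = acc)
}

# Run one chlorophyll/nitrogen scenario on a prepared base.
pipeline_scenario <- function(base, chl_multiplier = 1,
                              n_strategy = c("lhc_only", "constant_total_n")) {
  n_strategy <- match.arg(n_strategy)
  config <- base$config; mesh <- base$mesh; kinetics <- base$kinetics
  core <- kinetics$core_chl_psii * base$pools_default$psii +
    kinetics$core_chl_psi * base$pools_default$psi
  target <- pmax(chl_multiplier * chl_of_pools(base$pools_default, kinetics),
                 core + 1e-6)
  pools <- reallocate_nitrogen(base$pools_default, target, n_strategy,
                               kinetics)
  chl <- chl_of_pools(pools, kinetics)
  optics <- config_optics(config, chl)
  tv <- config$trace
  field <- if (chl_multiplier == 1 && n_strategy == "lhc_only")
    base$field
  else
    diurnal_light(mesh, optics, config$site$latitude,
                  config$site$day_of_year, config$site$time_step_h,
                  rays_per_m2 = tv$rays_per_m2, max_bounces = tv$max_bounces,
                  energy_cutoff = tv$energy_cutoff, seed = base$seed,
                  soil_reflectance = tv$soil_reflectance)
  nt <- length(field$times)
  a_mat <- matrix(0, nrow(field$incident), nt)
  for (t in seq_len(nt))
    a_mat[, t] <- leaf_assimilation(field$incident[, t], optics, pools,
                                    kinetics)
  dt_s <- field$time_step_h * 3600
  area <- mesh$facet_area
  daily_a <- rowSums(a_mat) * dt_s * 1e-6          # mol CO2 m-2 leaf d-1
  a_c <- sum(daily_a * area) / mesh$ground_area    # mol CO2 m-2 ground d-1
  n_tot <- nitrogen_of_pools(pools, kinetics)$total
  canopy_n <- sum(n_tot * area) / mesh$ground_area
  per_facet <- data.frame(
    facet = seq_along(area), rank = mesh$facet_rank, area = area,
    chl = chl, nla = base$nprofile$nla,
    daily_incident = rowSums(field$incident) * field$time_step_h,
    daily_absorbed = rowSums(field$absorbed) * field$time_step_h,
    daily_a = daily_a, photo_n = n_tot,
    p_max = base$acclimation$p_max, phi = base$acclimation$phi)
  structure(list(a_c_daily = a_c, canopy_photo_n = canopy_n,
                 nue = nue(a_c, canopy_n), chl_multiplier = chl_multiplier,
                 n_strategy = n_strategy,
                 mean_chl = stats::weighted.mean(chl, area),
                 per_facet = per_facet, field = field, pools = pools),
            class = "canopy_result")
}

#' Nitrogen use efficiency
#'
#' Daily canopy CO2 uptake per unit nitrogen invested in the seven
#' photosynthetic pools (leaf structural nitrogen excluded).
#'
#' @param a_c_daily Daily canopy uptake, mol CO2 m-2 ground d-1.
#' @param canopy_photo_n Photosynthetic nitrogen, g N m-2 ground.
#' @return NUE, mol CO2 (g N)-1 d-1.
#' @export
nue <- function(a_c_daily, canopy_photo_n) a_c_daily / canopy_photo_n

#' @export
print.canopy_result <- function(x, ...) {
  cat(sprintf("<canopy_result> chl x%.2f (%s): A_c %.4f mol m-2 d-1, N %.3f g m-2, NUE %.4f\n",
              x$chl_multiplier, x$n_strategy, x$a_c_daily, x$canopy_photo_n,
              x$nue))
  invisible(x)
}

#' Run the integrated canopy photosynthesis pipeline
#'
#' Executes the four stages in order — (1) canopy construction with
#' chlorophyll and optics, (2) diurnal Monte-Carlo ray trace, (3) light-driven
#' nitrogen profile, (4) per-leaf photo-acclimation, then the configured
#' chlorophyll scenario and time-resolved leaf assimilation — and integrates
#' to daily canopy CO2 uptake.  Fully reproducible from `(config, seed)`.
#'
#' @param config A [default_config()]-style configuration.
#' @param seed Integer seed for canopy jitter and ray tracing.
#' @return A `canopy_result`: `a_c_daily` (mol CO2 m-2 ground d-1),
#'   `canopy_photo_n` (g N m-2 ground), `nue`, `per_facet` table, the traced
#'   `field` and the scenario `pools`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L) {
  base <- pipeline_base(config, seed)
  pipeline_scenario(base, config$chl$multiplier, config$scenario$n_strategy)
}

#' Chlorophyll-multiplier sweep
#'
#' Re-runs the scenario stage for every (multiplier, strategy) cell on a
#' shared base run (the growth light, nitrogen profile and acclimation are
#' those of the default canopy; chlorophyll is then modified through the
#' antenna route).  Reports absolute and relative-to-default A_c and NUE.
#'
#' @param config A configuration.
#' @param multipliers Chlorophyll multipliers (default the canonical
#'   0.4-1.2 series).
#' @param strategies Nitrogen strategies to cross with the multipliers.
#' @param seed Integer seed.
#' @param base Optional precomputed [pipeline_base()] (internal reuse).
#' @return Object of class `chl_sweep`: data frame with `multiplier`,
#'   `strategy`, `a_c`, `canopy_n`, `nue`, `d_a_c_pct`, `d_nue_pct`, plus the
#'   per-cell results in `attr(, "results")`.
#' @export
run_chl_sweep <- function(config = default_config(),
                          multipliers = c(0.4, 0.6, 0.8, 1.0, 1.2),
                          strategies = c("lhc_only", "constant_total_n"),
                          seed = 1L, base = NULL) {
  stopifnot(all(multipliers > 0))
  if (is.null(base)) base <- pipeline_base(config, seed)
  ref <- pipeline_scenario(base, 1, "lhc_only")
  rows <- list(); results <- list()
  for (s in strategies) for (m in multipliers) {
    res <- if (m == 1) ref else pipeline_scenario(base, m, s)
    res$n_strategy <- s   # the m = 1 reference is strategy-independent
    key <- sprintf("%s_%g", s, m)
    results[[key]] <- res
    rows[[key]] <- data.frame(
      multiplier = m, strategy = s, a_c = res$a_c_daily,
      canopy_n = res$canopy_photo_n, nue = res$nue,
      d_a_c_pct = 100 * (res$a_c_daily / ref$a_c_daily - 1),
      d_nue_pct = 100 * (res$nue / ref$nue - 1))
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "results") <- results
  attr(out, "base") <- base
  class(out) <- c("chl_sweep", "data.frame")
  out
}

#' Architecture x latitude robustness sweep
#'
#' Crosses canopy architecture factors (leaf angle, plant height, LAI) with
#' latitudes, and for each cell compares the default canopy with a
#' reduced-chlorophyll scenario, flagging any cell where reduced chlorophyll
#' fails to increase A_c.
#'
#' @param config Base configuration.
#' @param angle_factors,height_factors,lai_factors Factor grids (default
#'   0.5 / 1.0 / 1.5).
#' @param latitudes Degrees north (default 45, 40, 31, 18).
#' @param chl_multiplier Reduced-chlorophyll level (default 0.4).
#' @param n_strategy Nitrogen strategy for the reduced level.
#' @param seed Integer seed.
#' @return Data frame with one row per cell: factors, latitude, `a_c_default`,
#'   `a_c_reduced`, `d_a_c_pct`, `benefit` (logical).
#' @export
run_architecture_sweep <- function(config = default_config(),
                                   angle_factors = c(0.5, 1, 1.5),
                                   height_factors = c(0.5, 1, 1.5),
                                   lai_factors = c(0.5, 1, 1.5),
                                   latitudes = c(45, 40, 31, 18),
                                   chl_multiplier = 0.4,
                                   n_strategy = "constant_total_n",
                                   seed = 1L) {
  grid <- expand.grid(angle = angle_factors, height = height_factors,
                      lai = lai_factors, latitude = latitudes)
  relations <- calibrate_linear_relations(kinetic_params())
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$canopy$angle_factor <- grid$angle[i]
    cfg$canopy$height_factor <- grid$height[i]
    cfg$canopy$lai_factor <- grid$lai[i]
    cfg$site$latitude <- grid$latitude[i]
    base <- pipeline_base(cfg, seed, relations = relations)
    ref <- pipeline_scenario(base, 1, "lhc_only")
    red <- pipeline_scenario(base, chl_multiplier, n_strategy)
    data.frame(grid[i, ], a_c_default = ref$a_c_daily,
               a_c_reduced = red$a_c_daily,
               d_a_c_pct = 100 * (red$a_c_daily / ref$a_c_daily - 1),
               benefit = red$a_c_daily >= ref$a_c_daily)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write tidy result tables and a run manifest
#'
#' @param results A `chl_sweep`, a `canopy_result`, or an architecture-sweep
#'   data frame.
#' @param dir Output directory (created if needed).
#' @param config,seed Provenance recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
report <- function(results, dir, config = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (inherits(results, "chl_sweep")) {
    wr(as.data.frame(results), "chl_sweep.csv")
    per <- lapply(attr(results, "results"), function(r)
      cbind(multiplier = r$chl_multiplier, strategy = r$n_strategy,
            r$per_facet))
    wr(do.call(rbind, c(per, make.row.names = FALSE)), "per_facet.csv")
  } else if (inherits(results, "canopy_result")) {
    wr(data.frame(a_c_daily = results$a_c_daily,
                  canopy_photo_n = results$canopy_photo_n,
                  nue = results$nue), "canopy_result.csv")
    wr(results$per_facet, "per_facet.csv")
  } else {
    wr(as.data.frame(results), "architecture_sweep.csv")
  }
  cfg_yaml <- if (!is.null(config)) yaml::as.yaml(unclass(config)) else NULL
  manifest <- list(package = "canophot",
                   version = as.character(utils::packageVersion("canophot")),
                   r_version = R.version.string,
                   seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
                   config_yaml = cfg_yaml)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, null = "null")
  invisible(c(paths, mp))
}
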