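# Solar geometry, clear-sky irradiance and the canopy light environment.

#' Solar position and clear-sky PPFD over a day
#'
#' Standard declination / hour-angle astronomy with a clear-sky two-stream
#' split: direct beam on a sun-normal plane
#' `I_dir = I0 * tau^m` and diffuse on horizontal
#' `I_dif = soc_fraction * (1 - tau^m) * I0 * cos(zenith)`, where `m` is the
#' relative air mass (1/cos zenith) and `I0` the extraterrestrial PPFD.  The
#' diffuse fraction of global irradiance therefore rises with solar zenith.
#' Both fluxes are zero when the sun is below the horizon.
#'
#' @param latitude Degrees, positive north, in `[-90, 90]`.
#' @param day_of_year Integer, 1-366.
#' @param time_step_h Time step, hours (> 0); steps are centred on local solar
#'   time from `time_step_h / 2` past midnight.
#' @param tau Atmospheric transmittance (default 0.75, clear sky).
#' @param i0 Extraterrestrial PPFD on a sun-normal plane, umol m-2 s-1
#'   (default 2600).
#' @param soc_fraction Scattered fraction reaching the ground as diffuse sky
#'   light (default 0.3).
#' @return Data frame of class `solar_course`: `hour`, `zenith`, `azimuth`
#'   (degrees), `direct_ppfd` (sun-normal), `diffuse_ppfd` (horizontal),
#'   `above_ppfd` (global horizontal).
#' @export
solar_course <- function(latitude, day_of_year, time_step_h = 0.5,
                         tau = 0.75, i0 = 2600, soc_fraction = 0.3) {
  stopifnot(latitude >= -90, latitude <= 90,
            day_of_year >= 1, day_of_year <= 366, time_step_h > 0)
  hours <- seq(time_step_h / 2, 24 - time_step_h / 2, by = time_step_h)
  # Spencer (1971) Fourier series for solar declination
  g <- 2 * pi * (day_of_year - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  lat <- latitude * pi / 180
  h_ang <- (hours - 12) * 15 * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(h_ang)
  cosz <- pmin(1, pmax(-1, cosz))
  zen <- acos(cosz)
  # azimuth measured clockwise from north
  az <- atan2(sin(h_ang), cos(h_ang) * sin(lat) - tan(decl) * cos(lat)) + pi
  up <- cosz > 1e-6
  am <- ifelse(up, 1 / pmax(cosz, 0.05), Inf)
  direct <- ifelse(up, i0 * tau^am, 0)
  diffuse <- ifelse(up, soc_fraction * (1 - tau^am) * i0 * cosz, 0)
  out <- data.frame(hour = hours, zenith = zen * 180 / pi,
                    azimuth = az * 180 / pi, direct_ppfd = direct,
                    diffuse_ppfd = diffuse,
                    above_ppfd = direct * pmax(cosz, 0) + diffuse)
  class(out) <- c("solar_course", "data.frame")
  out
}

#' A single solar state
#'
#' @param zenith,azimuth Solar position, degrees (azimuth clockwise from
#'   north).
#' @param direct_ppfd Direct-beam PPFD on a sun-normal plane, umol m-2 s-1.
#' @param diffuse_ppfd Diffuse sky PPFD on horizontal, umol m-2 s-1.
#' @return Object of class `solar_state`.
#' @export
solar_state <- function(zenith, azimuth = 180, direct_ppfd = 0,
                        diffuse_ppfd = 0) {
  stopifnot(zenith >= 0, zenith <= 180, direct_ppfd >= 0, diffuse_ppfd >= 0)
  if (zenith >= 90 && (direct_ppfd > 0 || diffuse_ppfd > 0))
    stop("sun below horizon: fluxes must be zero")
  structure(list(zenith = zenith, azimuth = azimuth,
                 direct_ppfd = direct_ppfd, diffuse_ppfd = diffuse_ppfd),
            class = "solar_state")
}

# sun travel direction (unit vector pointing from the sun toward the ground)
sun_direction <- function(zenith, azimuth) {
  z <- zenith * pi / 180; a <- azimuth * pi / 180
  # x = east, y = north
  -c(sin(z) * sin(a), sin(z) * cos(a), cos(z))
}

default_grid_dims <- function(mesh) {
  span_x <- mesh$ground_bounds[2] - mesh$ground_bounds[1]
  span_y <- mesh$ground_bounds[4] - mesh$ground_bounds[3]
  zmax <- max(mesh$vertices[, 3]) + 0.05
  # aim for a handful of triangles per cell
  cell <- max(0.02, (mesh$ground_area * zmax / max(1, nrow(mesh$triangles)) * 8)^(1 / 3))
  c(max(2L, ceiling(span_x / cell)), max(2L, ceiling(span_y / cell)),
    max(2L, ceiling(zmax / cell)))
}

#' Trace one solar state through a canopy
#'
#' Launches `rays_per_m2 * plot area` direct-beam rays (if the sun is up) and
#' the same number of diffuse sky rays, splitting energy at each hit into
#' absorbed / reflected / transmitted per the facet optics and following
#' scattered rays Lambertian up to `max_bounces` with a relative energy
#' cutoff.  The plot is horizontally periodic; soil is Lambertian with
#' reflectance `soil_reflectance`.  The estimator is unbiased: expected
#' per-facet fluxes do not depend on the ray density.
#'
#' @param mesh A `canopy_mesh`.
#' @param optics A [leaf_optics()] whose fields are scalars (applied to every
#'   facet) or per-facet vectors.
#' @param sun A [solar_state()].
#' @param rays_per_m2 Ray density per launch category, rays m-2 of plot.
#' @param max_bounces Scattering depth (default 2).
#' @param energy_cutoff Child rays below this fraction of a primary ray's
#'   energy are dropped into the `residual` bucket (default 0.01).
#' @param seed Integer RNG seed (tracing is reproducible given the seed).
#' @param soil_reflectance Soil Lambertian reflectance (default 0).
#' @return Object of class `trace_result`: per-facet `incident` and
#'   `absorbed` PPFD (umol m-2 facet s-1), per-facet power equivalents, and
#'   the energy ledger `soil_absorbed`, `escaped`, `residual`, `incoming`
#'   (umol s-1 over the plot).
#' @export
trace_canopy <- function(mesh, optics, sun, rays_per_m2 = 1e4,
                         max_bounces = 2L, energy_cutoff = 0.01, seed = 1L,
                         soil_reflectance = 0) {
  stopifnot(inherits(mesh, "canopy_mesh"), inherits(optics, "leaf_optics"),
            inherits(sun, "solar_state"), rays_per_m2 > 0)
  m <- nrow(mesh$triangles)
  refl <- rep_len(optics$reflectance, m)
  trans <- rep_len(optics$transmittance, m)
  if (any(refl + trans >= 1)) stop("non-physical optics: r + t must be < 1")
  res <- trace_cpp(mesh$vertices, mesh$triangles, refl, trans,
                   sun_direction(sun$zenith, sun$azimuth),
                   sun$direct_ppfd, sun$diffuse_ppfd,
                   mesh$ground_bounds, soil_reflectance, rays_per_m2,
                   as.integer(max_bounces), energy_cutoff, as.integer(seed),
                   as.integer(default_grid_dims(mesh)))
  if (res$n_degenerate > 0)
    warning(sprintf("%d degenerate triangle(s) skipped", res$n_degenerate))
  structure(list(incident = res$incident_power / mesh$facet_area,
                 absorbed = res$absorbed_power / mesh$facet_area,
                 incident_power = res$incident_power,
                 absorbed_power = res$absorbed_power,
                 soil_absorbed = res$soil_absorbed, escaped = res$escaped,
                 residual = res$residual, incoming = res$incoming),
            class = "trace_result")
}

#' Diurnal canopy light field
#'
#' Runs [trace_canopy()] for every daylit step of a [solar_course()] and
#' collects per-facet incident and absorbed PPFD into facet x time matrices.
#' Night steps are kept as zero columns so the time axis covers the full day.
#'
#' @param mesh A `canopy_mesh`.
#' @param optics A [leaf_optics()] (scalar or per-facet).
#' @param latitude,day_of_year,time_step_h Passed to [solar_course()].
#' @param rays_per_m2,max_bounces,energy_cutoff,seed,soil_reflectance Passed
#'   to [trace_canopy()]; the seed is advanced per time step so steps are
#'   independent but the whole field is reproducible.
#' @param course Optionally a precomputed [solar_course()] (overrides
#'   `latitude` / `day_of_year` / `time_step_h`).
#' @return Object of class `light_field`: `times` (h), `incident` and
#'   `absorbed` (facet x time, umol m-2 s-1), `above_ppfd` (global horizontal
#'   per step), `soil_absorbed` / `escaped` / `residual` / `incoming` (per
#'   step, umol s-1), `time_step_h`.
#' @export
diurnal_light <- function(mesh, optics, latitude = 31, day_of_year = 235,
                          time_step_h = 0.5, rays_per_m2 = 1e4,
                          max_bounces = 2L, energy_cutoff = 0.01, seed = 1L,
                          soil_reflectance = 0, course = NULL) {
  if (is.null(course))
    course <- solar_course(latitude, day_of_year, time_step_h)
  nt <- nrow(course)
  m <- nrow(mesh$triangles)
  incident <- matrix(0, m, nt)
  absorbed <- matrix(0, m, nt)
  soil <- esc <- resid <- inc <- numeric(nt)
  for (i in seq_len(nt)) {
    if (course$direct_ppfd[i] <= 0 && course$diffuse_ppfd[i] <= 0) next
    sun <- solar_state(course$zenith[i], course$azimuth[i],
                       course$direct_ppfd[i], course$diffuse_ppfd[i])
    tr <- trace_canopy(mesh, optics, sun, rays_per_m2, max_bounces,
                       energy_cutoff, seed = seed + i,
                       soil_reflectance = soil_reflectance)
    incident[, i] <- tr$incident
    absorbed[, i] <- tr$absorbed
    soil[i] <- tr$soil_absorbed; esc[i] <- tr$escaped
    resid[i] <- tr$residual; inc[i] <- tr$incoming
  }
  structure(list(times = course$hour, incident = incident,
                 absorbed = absorbed, above_ppfd = course$above_ppfd,
                 soil_absorbed = soil, escaped = esc, residual = resid,
                 incoming = inc, time_step_h = course$hour[2] - course$hour[1]),
            class = "light_field")
}

#' @export
print.light_field <- function(x, ...) {
  cat(sprintf("<light_field> %d facets x %d steps (%.2g h), %d daylit\n",
              nrow(x$incident), length(x$times), x$time_step_h,
              sum(x$above_ppfd > 0)))
  invisible(x)
}

#' Export a light field as long-format CSV
#'
#' @param field A [diurnal_light()] field.
#' @param path Output CSV path; columns `facet_id`, `time`, `incident_ppfd`,
#'   `absorbed_ppfd`.
#' @return Invisibly, `path`.
#' @export
write_light_field <- function(field, path) {
  m <- nrow(field$incident); nt <- length(field$times)
  df <- data.frame(facet_id = rep(seq_len(m), nt),
                   time = rep(field$times, each = m),
                   incident_ppfd = as.vector(field$incident),
                   absorbed_ppfd = as.vector(field$absorbed))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# facets ordered from the canopy top; cumulative LAI at facet midpoints
cum_lai_order <- function(mesh) {
  ord <- order(mesh$facet_centroid[, 3], decreasing = TRUE)
  area <- mesh$facet_area[ord]
  cl <- (cumsum(area) - area / 2) / mesh$ground_area
  list(order = ord, cum_lai = cl)
}

#' Beer's-law extinction coefficient from a traced light field
#'
#' Bins facets by cumulative LAI from the canopy top (height-ordered), takes
#' the area-weighted mean PPFD per bin, and fits
#' `PPFD(L) = I0 * exp(-k * L)` by least squares on the log of the bin means.
#'
#' @param field A [diurnal_light()] field.
#' @param mesh The `canopy_mesh` it was traced on.
#' @param time_index Daylit time-step index.
#' @param bins Number of cumulative-LAI bins (default 10).
#' @param measure Fit `"absorbed"` (default, as in canopy practice) or
#'   `"incident"` PPFD.
#' @return Object of class `extinction_fit`: `k`, `r_squared`, `bin_lai`,
#'   `bin_ppfd`.
#' @export
fit_extinction <- function(field, mesh, time_index, bins = 10,
                           measure = c("absorbed", "incident")) {
  measure <- match.arg(measure)
  if (field$above_ppfd[time_index] <= 0)
    stop("time_index is not a daylit step")
  flux <- field[[measure]][, time_index]
  co <- cum_lai_order(mesh)
  flux <- flux[co$order]; area <- mesh$facet_area[co$order]
  lai_max <- max(co$cum_lai)
  edges <- seq(0, lai_max, length.out = bins + 1)
  bin <- cut(co$cum_lai, edges, include.lowest = TRUE, labels = FALSE)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  mean_flux <- vapply(seq_len(bins), function(b) {
    idx <- which(bin == b)
    if (!length(idx)) return(NA_real_)
    stats::weighted.mean(flux[idx], area[idx])
  }, 0)
  ok <- !is.na(mean_flux) & mean_flux > 0
  if (sum(ok) < 3) stop("fewer than 3 non-empty bins with positive PPFD")
  fit <- stats::lm(log(mean_flux[ok]) ~ mids[ok])
  y <- log(mean_flux[ok])
  r2 <- 1 - sum(stats::resid(fit)^2) / max(sum((y - mean(y))^2), 1e-300)
  structure(list(k = -unname(stats::coef(fit)[2]), r_squared = r2,
                 bin_lai = mids, bin_ppfd = mean_flux),
            class = "extinction_fit")
}

#' @export
print.extinction_fit <- function(x, ...) {
  cat(sprintf("<extinction_fit> k = %.3f (R^2 = %.3f)\n", x$k, x$r_squared))
  invisible(x)
}

#' Mean PPFD in the top and bottom layers of a canopy
#'
#' Facets are ordered by height; the top and bottom layers hold the given
#' fraction of cumulative LAI.  Means are area-weighted incident PPFD,
#' averaged over all daylit steps unless a single `time_index` is given.
#'
#' @param field A [diurnal_light()] field.
#' @param mesh The traced `canopy_mesh`.
#' @param fraction Layer size as a fraction of total LAI, in `(0, 0.5)`.
#' @param time_index Optional single time step.
#' @return Named numeric `c(top =, bottom =)`, umol m-2 s-1.
#' @export
layer_means <- function(field, mesh, fraction = 0.2, time_index = NULL) {
  stopifnot(fraction > 0, fraction < 0.5)
  co <- cum_lai_order(mesh)
  lai_max <- max(co$cum_lai)
  top_idx <- co$order[co$cum_lai <= fraction * lai_max]
  bot_idx <- co$order[co$cum_lai >= (1 - fraction) * lai_max]
  if (!length(top_idx) || !length(bot_idx)) stop("empty layer")
  cols <- if (is.null(time_index)) which(field$above_ppfd > 0) else time_index
  mean_layer <- function(idx) {
    flux <- rowMeans(field$incident[idx, cols, drop = FALSE])
    stats::weighted.mean(flux, mesh$facet_area[idx])
  }
  c(top = mean_layer(top_idx), bottom = mean_layer(bot_idx))
}
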