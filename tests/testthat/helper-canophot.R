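# Shared fixtures.  Expensive objects (the linearised pool relations and a
# small pipeline base run) are built once per test session.

canophot_env <- new.env(parent = emptyenv())

cached_relations <- function() {
  if (is.null(canophot_env$relations))
    canophot_env$relations <- calibrate_linear_relations(kinetic_params())
  canophot_env$relations
}

# a small but structurally complete stand: 2 x 2 plants, hourly steps
small_config <- function() {
  cfg <- default_config()
  cfg$canopy$plants_x <- 2
  cfg$canopy$plants_y <- 2
  cfg$canopy$tillers <- 6
  cfg$site$time_step_h <- 1
  cfg$trace$rays_per_m2 <- 8e3
  cfg
}

cached_base <- function() {
  if (is.null(canophot_env$base))
    canophot_env$base <- canophot:::pipeline_base(small_config(), seed = 42,
                                                  relations = cached_relations())
  canophot_env$base
}

# half-sine diurnal PPFD course (peak at solar noon, 12 h photoperiod)
half_sine_course <- function(peak = 1800, step = 0.5) {
  hours <- seq(step / 2, 24 - step / 2, by = step)
  ppfd <- ifelse(hours > 6 & hours < 18,
                 peak * sin((hours - 6) / 12 * pi), 0)
  data.frame(hour = hours, ppfd = ppfd)
}
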