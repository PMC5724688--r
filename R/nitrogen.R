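# Vertical nitrogen distribution through the canopy, driven by the diurnal
# light profile: leaves seeing the flag-leaf light level carry flag-leaf
# nitrogen; nitrogen relaxes toward the basal value as light fades with depth.

#' Nitrogen distribution parameters
#'
#' @param nla_flag Flag-leaf nitrogen per leaf area, g N m-2 (must exceed
#'   `n_b`).
#' @param n_b Basal leaf nitrogen per leaf area, g N m-2.
#' @param beta,alpha Coefficients of the light-to-nitrogen allometry
#'   ([b_from_gai()]).
#' @param form `"power"` (default) or `"linear"` form of that allometry.
#' @return Object of class `nitrogen_params`.
#' @export
nitrogen_params <- function(nla_flag = 1.6, n_b = 0.4, beta = 0.8,
                            alpha = 0.45, form = c("power", "linear")) {
  form <- match.arg(form)
  stopifnot(nla_flag > n_b, n_b >= 0)
  structure(list(nla_flag = nla_flag, n_b = n_b, beta = beta, alpha = alpha,
                 form = form),
            class = "nitrogen_params")
}

#' Nitrogen-vs-light extinction ratio from green area index
#'
#' `b` is the ratio of the canopy extinction coefficients of nitrogen and
#' light.  Power form (default): `b = beta * GAI^(-alpha)` — the nitrogen
#' gradient weakens relative to the light gradient in denser canopies.
#' Linear form: `b = beta * GAI - alpha`.  Clamped at zero.
#'
#' @param gai Green area index (> 0).
#' @param beta,alpha Coefficients.
#' @param form `"power"` or `"linear"`.
#' @return `b`, dimensionless, >= 0.
#' @export
b_from_gai <- function(gai, beta = 0.8, alpha = 0.45,
                       form = c("power", "linear")) {
  form <- match.arg(form)
  stopifnot(gai > 0)
  b <- if (form == "power") beta * gai^(-alpha) else beta * gai - alpha
  max(0, b)
}

#' Per-facet nitrogen from the canopy light profile
#'
#' For each facet, `N_LA = (N_LA_flag - n_b) * (I_l / I_lfl)^b + n_b`, where
#' `I_l` is the facet's daily integral of incident PPFD and `I_lfl` the same
#' quantity for the middle of the flag-leaf layer (the median-height tercile
#' of rank-1 facets).  Only light ratios enter, so the profile is invariant
#' to a uniform rescaling of the light field, and `N_LA` is bounded by
#' `[n_b, nla_flag]`.
#'
#' @param field A [diurnal_light()] field.
#' @param mesh The traced `canopy_mesh`.
#' @param params A [nitrogen_params()].
#' @param gai Green area index used for `b`; default [mesh_lai()] of the
#'   mesh.
#' @return Object of class `nitrogen_profile`: `nla` (g N m-2 leaf, per
#'   facet), `total_canopy_n` (g N m-2 ground), `b`, `i_ratio` (per facet).
#' @export
nitrogen_profile <- function(field, mesh, params = nitrogen_params(),
                             gai = mesh_lai(mesh)) {
  stopifnot(inherits(params, "nitrogen_params"))
  daily <- rowSums(field$incident) * field$time_step_h   # umol m-2 (x3600)
  flag <- which(mesh$facet_rank == 1)
  if (!length(flag)) stop("no rank-1 (flag leaf) facets in mesh")
  # middle of the flag-leaf layer: median-height tercile of rank-1 facets
  z <- mesh$facet_centroid[flag, 3]
  qs <- stats::quantile(z, c(1 / 3, 2 / 3))
  mid <- flag[z >= qs[1] & z <= qs[2]]
  if (!length(mid)) mid <- flag
  i_lfl <- stats::weighted.mean(daily[mid], mesh$facet_area[mid])
  if (i_lfl <= 0) stop("flag-leaf layer received no light (I_lfl = 0)")
  b <- b_from_gai(gai, params$beta, params$alpha, params$form)
  ratio <- pmin(daily / i_lfl, 1)
  nla <- (params$nla_flag - params$n_b) * ratio^b + params$n_b
  structure(list(nla = nla,
                 total_canopy_n = sum(nla * mesh$facet_area) / mesh$ground_area,
                 b = b, i_ratio = ratio),
            class = "nitrogen_profile")
}

#' @export
print.nitrogen_profile <- function(x, ...) {
  cat(sprintf("<nitrogen_profile> b = %.3f, N_LA range %.2f-%.2f g m-2, canopy N %.2f g m-2 ground\n",
              x$b, min(x$nla), max(x$nla), x$total_canopy_n))
  invisible(x)
}
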