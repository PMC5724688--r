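# Reduced mechanistic leaf photosynthesis model.
#
# A steady-state Farquhar-type core whose capacities derive from seven
# photosynthetic protein pools through Vmax = kcat * c, with light input
# passed through a PSII excitation-energy partition submodel (photochemistry /
# regulated heat / fluorescence).  It exposes the same interface a full
# kinetic electron-transport + carbon-metabolism network would: net CO2
# uptake, partition fractions, and P_max / phi dependence on the pools.

#' Photosynthetic protein pools of a leaf
#'
#' Seven groups: Rubisco; other Calvin-Benson-cycle enzymes (CE); electron
#' transport chain + ATP synthase (ETCF); PSII and PSI reaction-centre
#' complexes; and the peripheral light-harvesting complexes LHCII / LHCI
#' (counted in LHC units of 14 chlorophylls).  Within-group stoichiometries
#' are fixed; the groups are the resolution at which nitrogen is allocated.
#'
#' @param rubisco,ce,etcf Protein amounts, g m-2.
#' @param psii,psi Reaction-centre complex concentrations, umol m-2.
#' @param lhcii,lhci Peripheral LHC unit concentrations, umol m-2.
#' @return Object of class `enzyme_pools` (fields may be equal-length
#'   vectors for batched leaves).
#' @export
enzyme_pools <- function(rubisco, ce, etcf, psii, psi, lhcii, lhci) {
  stopifnot(all(rubisco >= 0), all(ce >= 0), all(etcf >= 0), all(psii >= 0),
            all(psi >= 0), all(lhcii >= 0), all(lhci >= 0))
  structure(list(rubisco = rubisco, ce = ce, etcf = etcf, psii = psii,
                 psi = psi, lhcii = lhcii, lhci = lhci),
            class = "enzyme_pools")
}

#' @export
print.enzyme_pools <- function(x, ...) {
  cat("<enzyme_pools> (first element)\n")
  cat(sprintf("  Rubisco %.3f, CE %.3f, ETCF %.3f g m-2\n",
              x$rubisco[1], x$ce[1], x$etcf[1]))
  cat(sprintf("  PSII %.3f, PSI %.3f, LHCII %.2f, LHCI %.2f umol m-2 (chl %.1f)\n",
              x$psii[1], x$psi[1], x$lhcii[1], x$lhci[1], chl_of_pools(x)[1]))
  invisible(x)
}

#' Kinetic and composition constants of the pool groups
#'
#' Catalytic constants turn pool amounts into capacities (Vmax = kcat * c);
#' molecular weights and nitrogen fractions turn pools into nitrogen.
#' Defaults are literature-typical C3 values: Rubisco 3.5 s-1 per site, 8
#' sites, 550 kDa; lumped CE and ETCF capacity coefficients scaled so the
#' reference leaf ([reference_pools()]) is near co-limitation with
#' Jmax/Vcmax ~ 1.8; complex masses PSII 350 kDa, PSI 360 kDa, 25 kDa per
#' 14-chlorophyll LHC unit; 16% N in protein; 4 N atoms per chlorophyll.
#'
#' @param kcat_rubisco Rubisco turnover per catalytic site, s-1.
#' @param rubisco_sites Catalytic sites per holoenzyme.
#' @param mw_rubisco Rubisco molecular weight, g mol-1.
#' @param k_ce CE capacity coefficient, umol CO2 g-1 s-1.
#' @param k_etcf ETCF electron-transport coefficient, umol e- g-1 s-1.
#' @param n_frac_protein g N per g protein.
#' @param mw_psii,mw_psi,mw_lhc Complex masses, g mol-1.
#' @param chl_n_per_umol g N per umol chlorophyll (4 N per molecule).
#' @param core_chl_psii,core_chl_psi,chl_per_lhc Chlorophylls per complex.
#' @param ci Intercellular CO2, umol mol-1 (0.7 x 400 ppm; no stomatal
#'   model).
#' @param gamma_star,kc,ko,o2 Rubisco CO2/O2 kinetics at 25 C.
#' @param psii_share Fraction of leaf-absorbed PPFD delivered to PSII.
#' @param k_p,k_f,k_h0 Rate constants for photochemistry, fluorescence and
#'   basal heat in open PSII centres (dark-adapted photochemical yield
#'   k_p/(k_p+k_f+k_h0) ~ 0.83).
#' @param k_h_npq Regulated heat rate constant in closed centres.
#' @param k_psii Maximum electron turnover per PSII complex, e- s-1 (caps the
#'   chain when reaction centres, not antenna, are removed).
#' @param rd_frac Dark respiration as a fraction of Vcmax.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(kcat_rubisco = 3.5, rubisco_sites = 8,
                           mw_rubisco = 550000, k_ce = 100, k_etcf = 260,
                           n_frac_protein = 0.16, mw_psii = 350000,
                           mw_psi = 360000, mw_lhc = 25000,
                           chl_n_per_umol = 5.6e-5, core_chl_psii = 37,
                           core_chl_psi = 95, chl_per_lhc = 14, ci = 280,
                           gamma_star = 42.75, kc = 404.9, ko = 278.4,
                           o2 = 210, psii_share = 0.5, k_p = 1, k_f = 0.05,
                           k_h0 = 0.155, k_h_npq = 3, k_psii = 300,
                           rd_frac = 0.015) {
  k <- as.list(environment())
  stopifnot(all(unlist(k) > 0))
  structure(k, class = "kinetic_params")
}

#' Maximum catalytic rate of an enzyme pool
#'
#' `Vmax = kcat * c`: units propagate (e.g. kcat in s-1 and c in umol m-2
#' give Vmax in umol m-2 s-1).
#'
#' @param kcat Catalytic constant, s-1 (per site).
#' @param c Concentration of catalytic sites, umol m-2.
#' @return Vmax, umol m-2 s-1.
#' @export
vmax <- function(kcat, c) {
  stopifnot(all(kcat >= 0), all(c >= 0))
  kcat * c
}

#' Chlorophyll held by a pool set
#'
#' Generalisation of the antenna bookkeeping to independent LHC pools:
#' `Chl = 37 PSII + 95 PSI + 14 (LHCII + LHCI)` with the shipped core sizes.
#'
#' @param pools An [enzyme_pools()].
#' @param kinetics A [kinetic_params()].
#' @return Chlorophyll, umol m-2.
#' @export
chl_of_pools <- function(pools, kinetics = kinetic_params()) {
  kinetics$core_chl_psii * pools$psii + kinetics$core_chl_psi * pools$psi +
    kinetics$chl_per_lhc * (pools$lhcii + pools$lhci)
}

#' Nitrogen held by each pool group
#'
#' Protein nitrogen (mass x 16%) plus the nitrogen in bound chlorophyll.
#'
#' @param pools An [enzyme_pools()].
#' @param kinetics A [kinetic_params()].
#' @return List with `per_group` (named, g N m-2; vectors for batched pools)
#'   and `total`.
#' @export
nitrogen_of_pools <- function(pools, kinetics = kinetic_params()) {
  kk <- kinetics
  f <- kk$n_frac_protein
  per <- list(
    rubisco = pools$rubisco * f,
    ce = pools$ce * f,
    etcf = pools$etcf * f,
    psii = pools$psii * (kk$mw_psii * f * 1e-6 +
                           kk$core_chl_psii * kk$chl_n_per_umol),
    psi = pools$psi * (kk$mw_psi * f * 1e-6 +
                         kk$core_chl_psi * kk$chl_n_per_umol),
    lhcii = pools$lhcii * (kk$mw_lhc * f * 1e-6 +
                             kk$chl_per_lhc * kk$chl_n_per_umol),
    lhci = pools$lhci * (kk$mw_lhc * f * 1e-6 +
                           kk$chl_per_lhc * kk$chl_n_per_umol))
  list(per_group = per,
       total = per$rubisco + per$ce + per$etcf + per$psii + per$psi +
         per$lhcii + per$lhci)
}

#' Reference leaf pool composition
#'
#' A healthy cereal flag leaf: Vcmax ~ 102 umol m-2 s-1, Jmax/Vcmax ~ 1.8,
#' PSII 1 umol m-2, PSI/PSII 1.4, antenna size n1 = 9.66 LHC units per
#' photosystem so total chlorophyll is 494.6 umol m-2.
#'
#' @param kinetics A [kinetic_params()].
#' @param n1 Antenna size, LHC units per photosystem.
#' @param psii PSII concentration, umol m-2.
#' @return An [enzyme_pools()].
#' @export
reference_pools <- function(kinetics = kinetic_params(), n1 = 9.66,
                            psii = 1.0) {
  psi <- 1.4 * psii
  enzyme_pools(rubisco = 2.0, ce = 1.0, etcf = 0.7, psii = psii, psi = psi,
               lhcii = n1 * psii, lhci = n1 * psi)
}

# Capacity terms (vectorised over pool vectors)
vcmax_eff <- function(pools, kinetics) {
  kk <- kinetics
  vc_rub <- vmax(kk$kcat_rubisco,
                 kk$rubisco_sites * pools$rubisco / kk$mw_rubisco * 1e6)
  pmin(vc_rub, kk$k_ce * pools$ce)
}
jmax_etcf <- function(pools, kinetics) kinetics$k_etcf * pools$etcf

# Maximum electron flux the downstream chain + carbon metabolism can accept
# at the operating Ci (umol e- m-2 s-1).
psii_sink_capacity <- function(pools, kinetics = kinetic_params()) {
  kk <- kinetics
  km <- kk$kc * (1 + kk$o2 / kk$ko)
  vc <- vcmax_eff(pools, kinetics)
  pmin(jmax_etcf(pools, kinetics), kk$k_psii * pools$psii,
       4 * vc * (kk$ci + 2 * kk$gamma_star) / (kk$ci + km))
}

#' Excitation-energy partition at PSII
#'
#' Balances excitation delivery against downstream electron-sink capacity.
#' Photons reaching PSII arrive at rate `psii_share * absorbance * PPFD`; a
#' fraction `q` of centres remains open in steady state, photochemistry
#' proceeding with the open-centre yield `k_p / (k_p + k_f + k_h0)` and
#' closed centres dissipating by regulated heat (`k_h_npq`).  Fractions are
#' of the PPFD absorbed by PSII and sum to 1 exactly.
#'
#' @param incident_ppfd Incident PPFD, umol m-2 s-1 (vectorised).
#' @param optics A [leaf_optics()].
#' @param pools An [enzyme_pools()] (sets the electron sink).
#' @param kinetics A [kinetic_params()].
#' @param sink_capacity Optional electron-sink override, umol e- m-2 s-1.
#' @return Object of class `energy_partition` with vector fields
#'   `f_photochemistry`, `f_heat`, `f_fluorescence`, `q_open` and
#'   `absorbed_psii` (umol m-2 s-1).
#' @export
psii_partition <- function(incident_ppfd, optics, pools,
                           kinetics = kinetic_params(),
                           sink_capacity = NULL) {
  stopifnot(all(incident_ppfd >= 0))
  kk <- kinetics
  if (is.null(sink_capacity))
    sink_capacity <- psii_sink_capacity(pools, kinetics)
  ex <- kk$psii_share * optics$absorbance * incident_ppfd
  y_open <- kk$k_p / (kk$k_p + kk$k_f + kk$k_h0)
  # realised photochemical flux: hyperbolic co-limitation of excitation
  # supply (all centres open) and the downstream electron sink; centres
  # close progressively rather than abruptly
  supply <- ex * y_open
  th <- 0.92
  s <- supply + sink_capacity
  j <- (s - sqrt(pmax(0, s^2 - 4 * th * supply * sink_capacity))) / (2 * th)
  q <- ifelse(supply > 0, j / supply, 1)
  f_p <- q * y_open
  f_f <- q * kk$k_f / (kk$k_p + kk$k_f + kk$k_h0) +
    (1 - q) * kk$k_f / (kk$k_f + kk$k_h0 + kk$k_h_npq)
  structure(list(f_photochemistry = f_p, f_heat = 1 - f_p - f_f,
                 f_fluorescence = f_f, q_open = q, absorbed_psii = ex),
            class = "energy_partition")
}

#' Net leaf CO2 uptake from pools, optics and light
#'
#' `A = min(Wc, Wj) - Rd` with the Rubisco-limited rate
#' `Wc = Vcmax_eff (Ci - G*)/(Ci + Km)`, `Vcmax_eff` the Rubisco capacity
#' capped by the CE pool, and the regeneration-limited rate
#' `Wj = (J/4)(Ci - G*)/(Ci + 2G*)` driven by the realised PSII electron flux
#' `J = f_photochemistry x PPFD absorbed by PSII` (which the partition
#' submodel already caps by the ETCF-pool and Rubisco-side sink).  CO2/O2
#' kinetics at 25 C; fixed intercellular CO2.
#'
#' @param incident_ppfd Incident PPFD, umol m-2 s-1 (vectorised).
#' @param optics A [leaf_optics()] (scalar or parallel vectors).
#' @param pools An [enzyme_pools()] (scalar or parallel vectors).
#' @param kinetics A [kinetic_params()].
#' @return Net CO2 uptake, umol m-2 s-1 (vector).
#' @export
leaf_assimilation <- function(incident_ppfd, optics, pools,
                              kinetics = kinetic_params()) {
  kk <- kinetics
  part <- psii_partition(incident_ppfd, optics, pools, kinetics)
  j <- part$f_photochemistry * part$absorbed_psii
  km <- kk$kc * (1 + kk$o2 / kk$ko)
  vc <- vcmax_eff(pools, kinetics)
  wc <- vc * (kk$ci - kk$gamma_star) / (kk$ci + km)
  wj <- j / 4 * (kk$ci - kk$gamma_star) / (kk$ci + 2 * kk$gamma_star)
  pmin(wc, wj) - kk$rd_frac * vc
}

#' Change the chlorophyll of a pool set
#'
#' `antenna_size` adjusts only the peripheral LHC pools (via the implied
#' antenna size n1, kept equal on both photosystems) at fixed reaction-centre
#' numbers; `ps_number` scales PSII, PSI, LHCII and LHCI together, preserving
#' antenna size.  Either way `chl_of_pools(result) = target_chl`.
#'
#' @param pools An [enzyme_pools()].
#' @param target_chl Target chlorophyll, umol m-2.
#' @param mode `"antenna_size"` or `"ps_number"`.
#' @param kinetics A [kinetic_params()].
#' @return Modified [enzyme_pools()].
#' @export
modify_chlorophyll <- function(pools, target_chl,
                               mode = c("antenna_size", "ps_number"),
                               kinetics = kinetic_params()) {
  mode <- match.arg(mode)
  kk <- kinetics
  if (mode == "antenna_size") {
    core <- kk$core_chl_psii * pools$psii + kk$core_chl_psi * pools$psi
    if (any(target_chl < core - 1e-9))
      stop(sprintf("target %.1f umol m-2 below core-only chlorophyll %.1f",
                   min(target_chl), max(core)))
    n1 <- (target_chl - core) / (kk$chl_per_lhc * (pools$psii + pools$psi))
    pools$lhcii <- n1 * pools$psii
    pools$lhci <- n1 * pools$psi
  } else {
    cur <- chl_of_pools(pools, kinetics)
    sc <- target_chl / cur
    pools$psii <- pools$psii * sc
    pools$psi <- pools$psi * sc
    pools$lhcii <- pools$lhcii * sc
    pools$lhci <- pools$lhci * sc
  }
  pools
}

#' Nonrectangular-hyperbola light-response parameters
#'
#' @param p_max Light-saturated gross assimilation asymptote, umol m-2 s-1.
#' @param phi Initial slope, mol CO2 per mol incident photons.
#' @param theta Curvature, in (0, 1).
#' @param r_d Dark respiration, umol m-2 s-1.
#' @return Object of class `light_response`.
#' @export
light_response <- function(p_max, phi, theta = 0.8, r_d = 1.0) {
  stopifnot(p_max > 0, phi > 0, phi < 0.125, theta > 0, theta < 1, r_d >= 0)
  structure(list(p_max = p_max, phi = phi, theta = theta, r_d = r_d),
            class = "light_response")
}

#' @export
print.light_response <- function(x, ...) {
  cat(sprintf("<light_response> P_max %.2f, phi %.4f, theta %.2f, R_d %.2f\n",
              x$p_max, x$phi, x$theta, x$r_d))
  invisible(x)
}

#' Evaluate a nonrectangular hyperbola
#'
#' `A(Q) = [phi Q + P_max - sqrt((phi Q + P_max)^2 - 4 theta phi Q P_max)] /
#' (2 theta) - R_d`.
#'
#' @param resp A [light_response()].
#' @param ppfd PPFD, umol m-2 s-1 (vectorised).
#' @return Net assimilation, umol m-2 s-1.
#' @export
nrh_predict <- function(resp, ppfd) {
  s <- resp$phi * ppfd + resp$p_max
  (s - sqrt(pmax(0, s^2 - 4 * resp$theta * resp$phi * ppfd * resp$p_max))) /
    (2 * resp$theta) - resp$r_d
}

#' Fit a nonrectangular hyperbola to a light-response curve
#'
#' Least-squares fit of all four parameters, with self-starting values
#' (initial slope from the low-light points, asymptote from the curve top).
#'
#' @param ppfd_points PPFD values, umol m-2 s-1 (>= 5, spanning sub- and
#'   supra-saturating light).
#' @param a_points Net assimilation, umol m-2 s-1.
#' @return A [light_response()] with attribute `"rss"`.
#' @export
fit_nrh <- function(ppfd_points, a_points) {
  stopifnot(length(ppfd_points) >= 5, length(ppfd_points) == length(a_points))
  ord <- order(ppfd_points)
  q <- ppfd_points[ord]; a <- a_points[ord]
  rd0 <- max(0, -min(a))
  # initial slope from the genuinely light-limited points
  qpos <- q[q > 0]
  low <- q > 0 & q <= max(stats::quantile(qpos, 0.25), qpos[min(2, length(qpos))])
  phi0 <- if (sum(low) >= 2)
    max(1e-3, min(0.12, stats::coef(stats::lm(I(a[low] - a[1]) ~ 0 + q[low]))[1]))
  else 0.05
  pmax0 <- max(a) + rd0 + 1e-3
  df <- data.frame(q = q, a = a)
  best <- NULL
  for (theta0 in c(0.5, 0.8, 0.95)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        a ~ (phi * q + pm - sqrt((phi * q + pm)^2 - 4 * theta * phi * q * pm)) /
          (2 * theta) - rd,
        data = df,
        start = list(pm = pmax0, phi = phi0, theta = theta0, rd = rd0),
        lower = c(1e-3, 1e-4, 0.01, 0),
        upper = c(200, 0.1249, 0.999, 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("NRH fit failed to converge from all starts")
  cf <- stats::coef(best$fit)
  out <- light_response(cf[["pm"]], cf[["phi"]], cf[["theta"]], cf[["rd"]])
  attr(out, "rss") <- best$rss
  out
}

# Simulate a light-response curve with the mechanistic leaf model and fit it.
simulate_and_fit <- function(pools, kinetics, chl = NULL,
                             q_grid = c(0, 25, 50, 100, 150, 250, 400, 600,
                                        900, 1200, 1600, 2000)) {
  if (is.null(chl)) chl <- chl_of_pools(pools, kinetics)
  optics <- optics_from_chl(chl)
  a <- leaf_assimilation(q_grid, optics, pools, kinetics)
  fit_nrh(q_grid, a)
}

#' Calibrate the linear pool-to-parameter relations
#'
#' Simulates light-response curves with the mechanistic leaf model over a
#' grid of pool compositions, fits each with [fit_nrh()], and regresses
#' `P_max` on Rubisco, CE and ETCF (co-scaled capacity grid) and `phi` on
#' PSII (co-scaled photosystem grid), yielding the four linear relations
#' `P_max = a_i * pool + b_i` (i = 1..3) and `phi = a4 * PSII + b4` used by
#' the acclimation optimizer.
#'
#' @param kinetics A [kinetic_params()].
#' @param reference An [enzyme_pools()] at the grid centre.
#' @param scales Multiplicative grid applied to the capacity pools and,
#'   separately, to the photosystem pools (default 0.7-1.3: the documented
#'   physiological range of the linearisation).
#' @return Object of class `pool_relations`: `coef` (data frame with
#'   `pool`, `a`, `b`, `r_squared`), plus the `theta` and `r_d` medians of
#'   the fits, the grids, and the inputs.
#' @export
calibrate_linear_relations <- function(kinetics = kinetic_params(),
                                       reference = reference_pools(kinetics),
                                       scales = seq(0.8, 1.2, by = 0.05)) {
  if (length(scales) < 3) stop("degenerate grid: need >= 3 scale points")
  cap_fits <- lapply(scales, function(s) {
    p <- reference
    p$rubisco <- p$rubisco * s; p$ce <- p$ce * s; p$etcf <- p$etcf * s
    simulate_and_fit(p, kinetics)
  })
  ps_fits <- lapply(scales, function(s) {
    p <- reference
    p$psii <- p$psii * s; p$psi <- p$psi * s
    p$lhcii <- p$lhcii * s; p$lhci <- p$lhci * s
    simulate_and_fit(p, kinetics)
  })
  pm <- vapply(cap_fits, `[[`, 0, "p_max")
  phi <- vapply(ps_fits, `[[`, 0, "phi")
  reg <- function(y, x) {
    fit <- stats::lm(y ~ x)
    r2 <- 1 - sum(stats::resid(fit)^2) / max(sum((y - mean(y))^2), 1e-300)
    c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
      r_squared = r2)
  }
  rows <- rbind(
    rubisco = reg(pm, reference$rubisco * scales),
    ce = reg(pm, reference$ce * scales),
    etcf = reg(pm, reference$etcf * scales),
    psii = reg(phi, reference$psii * scales))
  coef <- data.frame(pool = rownames(rows), rows, row.names = NULL)
  structure(list(coef = coef,
                 theta = stats::median(vapply(cap_fits, `[[`, 0, "theta")),
                 r_d = stats::median(vapply(cap_fits, `[[`, 0, "r_d")),
                 scales = scales, reference = reference,
                 kinetics = kinetics),
            class = "pool_relations")
}

#' @export
print.pool_relations <- function(x, ...) {
  cat("<pool_relations> P_max / phi vs pool (linearised):\n")
  print(x$coef, digits = 4)
  cat(sprintf("  theta = %.3f, R_d = %.3f\n", x$theta, x$r_d))
  invisible(x)
}
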